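# Cell-list neighbor searches. Pure R, vectorised per cell pair; the
# 12 A all-atom network of a ~9,000-atom globule (~1.3M pairs) lists in
# well under a second, so no compiled code is needed.

.cell_index <- function(xyz, cell_size) {
  floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell_size)
}

#' All atom pairs within a distance cutoff
#'
#' Cell-list search over a single coordinate set; results are identical
#' to the O(N^2) double loop (pairs with distance strictly below
#' `cutoff`, indices i < j).
#'
#' @param xyz n x 3 coordinate matrix (angstrom).
#' @param cutoff distance cutoff in angstrom.
#' @return data frame with columns `i`, `j` (1-based, i < j) and `r`.
#' @export
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), r = numeric(0)))
  cell <- .cell_index(xyz, cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cells <- split(seq_len(n), key)
  ckeys <- matrix(as.integer(do.call(rbind, strsplit(names(cells), " ", fixed = TRUE))), ncol = 3)
  cmap <- new.env(hash = TRUE, size = length(cells))
  for (ii in seq_along(cells)) assign(names(cells)[ii], ii, envir = cmap)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  acc_i <- vector("list", 64); acc_j <- vector("list", 64); acc_r <- vector("list", 64); na <- 0
  push <- function(pi, pj, pr) {
    na <<- na + 1
    if (na > length(acc_i)) {
      length(acc_i) <<- 2 * na; length(acc_j) <<- 2 * na; length(acc_r) <<- 2 * na
    }
    acc_i[[na]] <<- pi; acc_j[[na]] <<- pj; acc_r[[na]] <<- pr
  }
  c2 <- cutoff^2
  for (ii in seq_along(cells)) {
    A <- cells[[ii]]
    for (oo in seq_len(27)) {
      nk <- paste(ckeys[ii, 1] + offs[oo, 1], ckeys[ii, 2] + offs[oo, 2], ckeys[ii, 3] + offs[oo, 3])
      jj <- if (exists(nk, envir = cmap, inherits = FALSE)) get(nk, envir = cmap) else NULL
      if (is.null(jj) || jj < ii) next
      B <- cells[[jj]]
      if (jj == ii) {
        if (length(A) < 2) next
        d2 <- as.matrix(stats::dist(xyz[A, , drop = FALSE]))^2
        w <- which(upper.tri(d2) & d2 < c2, arr.ind = TRUE)
        if (nrow(w)) push(A[w[, 1]], A[w[, 2]], sqrt(d2[w]))
      } else {
        dx <- outer(xyz[A, 1], xyz[B, 1], "-")
        dy <- outer(xyz[A, 2], xyz[B, 2], "-")
        dz <- outer(xyz[A, 3], xyz[B, 3], "-")
        d2 <- dx * dx + dy * dy + dz * dz
        w <- which(d2 < c2, arr.ind = TRUE)
        if (nrow(w)) push(A[w[, 1]], B[w[, 2]], sqrt(d2[w]))
      }
    }
  }
  if (na == 0) return(data.frame(i = integer(0), j = integer(0), r = numeric(0)))
  i <- unlist(acc_i[seq_len(na)], use.names = FALSE)
  j <- unlist(acc_j[seq_len(na)], use.names = FALSE)
  r <- unlist(acc_r[seq_len(na)], use.names = FALSE)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], r = r[ord])
}

# Cross pairs between two coordinate sets within cutoff; returns indices
# into each set. Same cell-list scheme, B gridded, A queried.
.cross_pairs <- function(xa, xb, cutoff) {
  if (nrow(xa) == 0 || nrow(xb) == 0) {
    return(data.frame(ia = integer(0), ib = integer(0), r = numeric(0)))
  }
  origin <- pmin(apply(xa, 2, min), apply(xb, 2, min))
  cb <- floor(sweep(xb, 2, origin) / cutoff)
  keyb <- paste(cb[, 1], cb[, 2], cb[, 3])
  cellsb <- split(seq_len(nrow(xb)), keyb)
  ca <- floor(sweep(xa, 2, origin) / cutoff)
  keya <- paste(ca[, 1], ca[, 2], ca[, 3])
  cellsa <- split(seq_len(nrow(xa)), keya)
  akeys <- matrix(as.integer(do.call(rbind, strsplit(names(cellsa), " ", fixed = TRUE))), ncol = 3)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", length(cellsa) * 4); na <- 0
  c2 <- cutoff^2
  for (ii in seq_along(cellsa)) {
    A <- cellsa[[ii]]
    for (oo in seq_len(27)) {
      nk <- paste(akeys[ii, 1] + offs[oo, 1], akeys[ii, 2] + offs[oo, 2], akeys[ii, 3] + offs[oo, 3])
      B <- cellsb[[nk]]
      if (is.null(B)) next
      dx <- outer(xa[A, 1], xb[B, 1], "-")
      dy <- outer(xa[A, 2], xb[B, 2], "-")
      dz <- outer(xa[A, 3], xb[B, 3], "-")
      d2 <- dx * dx + dy * dy + dz * dz
      w <- which(d2 < c2, arr.ind = TRUE)
      if (nrow(w)) {
        na <- na + 1
        if (na > length(out)) length(out) <- 2 * na
        out[[na]] <- cbind(A[w[, 1]], B[w[, 2]], sqrt(d2[w]))
      }
    }
  }
  if (na == 0) return(data.frame(ia = integer(0), ib = integer(0), r = numeric(0)))
  m <- do.call(rbind, out[seq_len(na)])
  data.frame(ia = as.integer(m[, 1]), ib = as.integer(m[, 2]), r = m[, 3])
}
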