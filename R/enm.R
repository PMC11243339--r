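# Distance-weighted all-atom elastic network model.
#
# Heavy-atom pairs within a cutoff are joined by harmonic springs at
# their reference separations, with distance-weighted stiffness
#   k(r) = k0 * exp(1 - (r/r0)^2)
# (equal to k0 at r = r0, decaying with distance), multiplied by a cubic
# smoothstep that takes the stiffness smoothly to zero between
# switch_start and cutoff. Defaults: k0 = 100 kcal/(mol A^2), r0 = 5 A,
# cutoff 12 A, switch_start 10 A.

#' Distance-weighted spring stiffness
#'
#' `k(r) = k0 * exp(1 - (r/r0)^2)` for `r <= switch_start`, multiplied by
#' a cubic smoothstep falling from 1 to 0 over `[switch_start, cutoff]`,
#' exactly 0 at and beyond the cutoff. Vectorised over `rij`.
#'
#' @param rij pair distance(s), angstrom (> 0).
#' @param k0 stiffness scale, kcal/(mol A^2).
#' @param r0 distance-weight parameter, angstrom.
#' @param switch_start start of the smooth cutoff window, angstrom.
#' @param cutoff interaction cutoff, angstrom.
#' @return stiffness in kcal/(mol A^2).
#' @export
spring_constant <- function(rij, k0 = 100, r0 = 5, switch_start = 10, cutoff = 12) {
  if (any(rij <= 0)) stop("pair distance must be > 0")
  if (k0 <= 0 || r0 <= 0) stop("k0 and r0 must be > 0")
  if (!(switch_start < cutoff)) stop("switch_start must be < cutoff")
  k <- k0 * exp(1 - (rij / r0)^2)
  t <- pmin(pmax((rij - switch_start) / (cutoff - switch_start), 0), 1)
  k * (1 - (3 * t^2 - 2 * t^3))
}

#' Build the elastic spring network of a structure
#'
#' Every unordered heavy-atom pair with reference distance below
#' `cutoff` becomes a spring with rest length equal to that distance and
#' stiffness from `spring_fun` (default [spring_constant()]). Hydrogens
#' are stripped automatically (with a warning) if present; masses must
#' already be assigned.
#'
#' @param s a [mol_structure()] with masses assigned.
#' @param k0,r0,switch_start,cutoff model parameters (angstrom and
#'   kcal/(mol A^2)); defaults are the adopted model values.
#' @param spring_fun optional replacement stiffness function with the
#'   same signature as [spring_constant()].
#' @return an object of class `spring_network`: the structure, a pair
#'   table (`i`, `j`, `r0`, `k`) and the parameters.
#' @export
build_network <- function(s, k0 = 100, r0 = 5, switch_start = 10, cutoff = 12,
                          spring_fun = spring_constant) {
  if (any(toupper(s$atoms$element) %in% c("H", "D"))) {
    warning("structure contains hydrogens; stripping them for the network")
    s <- strip_hydrogens(s)
  }
  if (n_atoms(s) < 2) stop("need at least 2 atoms to build a network")
  if (any(is.na(s$atoms$mass))) {
    stop("masses not assigned; call assign_masses() first")
  }
  pr <- neighbor_pairs(coords(s), cutoff)
  if (nrow(pr) && any(pr$r < 1e-8)) stop("coincident atoms in the structure")
  k <- if (nrow(pr)) {
    spring_fun(pr$r, k0 = k0, r0 = r0, switch_start = switch_start, cutoff = cutoff)
  } else numeric(0)
  out <- list(
    structure = s,
    pairs = data.frame(i = pr$i, j = pr$j, r0 = pr$r, k = k),
    k0 = k0, r0 = r0, switch_start = switch_start, cutoff = cutoff
  )
  class(out) <- "spring_network"
  out
}

#' @export
print.spring_network <- function(x, ...) {
  cat("spring_network on '", x$structure$label, "': ", n_atoms(x$structure),
      " atoms, ", nrow(x$pairs), " springs (k0=", x$k0, ", r0=", x$r0,
      ", cutoff=", x$cutoff, " A)\n", sep = "")
  invisible(x)
}

#' Assemble the ENM Hessian
#'
#' Analytic second derivative of
#' `E = 1/2 * sum_pairs k_ij (|x_i - x_j| - r0_ij)^2`
#' at the reference configuration: the off-diagonal 3x3 block of pair
#' (i, j) is `-(k_ij / r0_ij^2) d_ij d_ij^T` with `d_ij` the reference
#' separation vector, and each diagonal block is minus the sum of its
#' row's off-diagonal blocks, which makes the matrix exactly symmetric,
#' translation-invariant and positive semi-definite.
#'
#' Atoms listed in `fixed` are treated as immobile anchors: their
#' degrees of freedom are removed, and springs from a free atom to an
#' anchor contribute only to the free atom's diagonal block (so the
#' potential is no longer translation-invariant and the rigid modes are
#' lifted).
#'
#' @param net a [build_network()] result.
#' @param fixed integer indices of anchored atoms (default none).
#' @return an object of class `enm_hessian` holding a sparse symmetric
#'   matrix over the free atoms' 3N coordinates.
#' @export
assemble_hessian <- function(net, fixed = integer(0)) {
  s <- net$structure
  n_all <- n_atoms(s)
  if (length(fixed)) {
    fixed <- sort(unique(as.integer(fixed)))
    if (any(fixed < 1 | fixed > n_all)) stop("fixed indices out of range")
  }
  free <- setdiff(seq_len(n_all), fixed)
  nf <- length(free)
  if (nf == 0) stop("all atoms fixed; no degrees of freedom left")
  remap <- integer(n_all); remap[free] <- seq_len(nf)
  xyz <- coords(s)
  P <- net$pairs
  if (nrow(P) && any(P$r0 < 1e-8)) stop("coincident atoms in a spring pair")
  dim3 <- 3 * nf
  if (nrow(P) == 0) {
    H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(dim3, dim3), symmetric = FALSE)
  } else {
    i_fix <- P$i %in% fixed; j_fix <- P$j %in% fixed
    keep <- !(i_fix & j_fix)              # anchor-anchor springs are inert
    P <- P[keep, , drop = FALSE]
    i_fix <- i_fix[keep]; j_fix <- j_fix[keep]
    d <- xyz[P$i, , drop = FALSE] - xyz[P$j, , drop = FALSE]
    kk <- P$k / P$r0^2
    np <- nrow(P)
    # per-pair 3x3 block, row-major: entries (a,b) of kk * d d^T
    bx <- as.numeric(t(cbind(
      kk * d[, 1] * d[, 1], kk * d[, 1] * d[, 2], kk * d[, 1] * d[, 3],
      kk * d[, 2] * d[, 1], kk * d[, 2] * d[, 2], kk * d[, 2] * d[, 3],
      kk * d[, 3] * d[, 1], kk * d[, 3] * d[, 2], kk * d[, 3] * d[, 3]
    )))
    pe <- rep(rep(1:3, each = 3), np)   # block row offset
    pt <- rep(rep(1:3, times = 3), np)  # block col offset
    ri <- rep(3 * (remap[P$i] - 1), each = 9)
    rj <- rep(3 * (remap[P$j] - 1), each = 9)
    both_free <- rep(!(i_fix | j_fix), each = 9)
    i_free_only <- rep(!i_fix & j_fix, each = 9)
    j_free_only <- rep(i_fix & !j_fix, each = 9)
    I <- c((ri + pe)[both_free], (rj + pe)[both_free],   # off-diagonal blocks
           (ri + pe)[both_free | i_free_only],           # diagonal block of i
           (rj + pe)[both_free | j_free_only])           # diagonal block of j
    J <- c((rj + pt)[both_free], (ri + pt)[both_free],
           (ri + pt)[both_free | i_free_only],
           (rj + pt)[both_free | j_free_only])
    X <- c(-bx[both_free], -bx[both_free],
           bx[both_free | i_free_only], bx[both_free | j_free_only])
    H <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(dim3, dim3))
  }
  out <- list(
    H = Matrix::forceSymmetric(H),
    structure = s,
    free_atoms = free,
    masses = s$atoms$mass[free],
    mass_weighted = FALSE,
    params = list(k0 = net$k0, r0 = net$r0, switch_start = net$switch_start,
                  cutoff = net$cutoff, fixed = fixed)
  )
  class(out) <- "enm_hessian"
  out
}

#' @export
print.enm_hessian <- function(x, ...) {
  cat("enm_hessian: ", nrow(x$H), " x ", nrow(x$H),
      if (x$mass_weighted) " (mass-weighted)" else "",
      ", nnz = ", length(x$H@x), "\n", sep = "")
  invisible(x)
}

#' Mass-weight a Hessian
#'
#' `H' = M^{-1/2} H M^{-1/2}` with M the diagonal matrix of atomic
#' masses (each coordinate inherits its atom's mass). Symmetry is
#' preserved exactly.
#'
#' @param h an [assemble_hessian()] result.
#' @param masses optional replacement masses (amu, one per free atom);
#'   defaults to the structure's assigned masses.
#' @return an `enm_hessian` with `mass_weighted = TRUE`.
#' @export
mass_weight <- function(h, masses = NULL) {
  if (h$mass_weighted) stop("Hessian is already mass-weighted")
  m <- if (is.null(masses)) h$masses else masses
  if (length(m) != nrow(h$H) / 3) stop("need one mass per free atom")
  if (any(is.na(m)) || any(m <= 0)) stop("all masses must be assigned and > 0")
  isq <- rep(1 / sqrt(m), each = 3)
  D <- Matrix::Diagonal(x = isq)
  h$H <- Matrix::forceSymmetric(D %*% h$H %*% D)
  h$masses <- m
  h$mass_weighted <- TRUE
  h
}

# Dense reference assembly (double loop); oracle for tests.
.dense_hessian <- function(net) {
  s <- net$structure
  n <- n_atoms(s)
  xyz <- coords(s)
  H <- matrix(0, 3 * n, 3 * n)
  P <- net$pairs
  for (p in seq_len(nrow(P))) {
    i <- P$i[p]; j <- P$j[p]
    d <- xyz[i, ] - xyz[j, ]
    B <- (P$k[p] / P$r0[p]^2) * tcrossprod(d)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - B
    H[jj, ii] <- H[jj, ii] - B
    H[ii, ii] <- H[ii, ii] + B
    H[jj, jj] <- H[jj, jj] + B
  }
  H
}

# ENM potential energy at arbitrary coordinates (for finite-difference
# oracles): E = 1/2 sum k (|xi-xj| - r0)^2 over the network's pairs.
.enm_energy <- function(net, xyz) {
  P <- net$pairs
  d <- sqrt(rowSums((xyz[P$i, , drop = FALSE] - xyz[P$j, , drop = FALSE])^2))
  sum(0.5 * P$k * (d - P$r0)^2)
}
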