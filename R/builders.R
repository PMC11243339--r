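# Honeycomb-lattice geometry generators for the carbon supports.
# C-C bond length 1.42 A; graphene lattice constant a = sqrt(3)*1.42 = 2.46 A.

.CC_BOND <- 1.42
.LATTICE_A <- sqrt(3) * .CC_BOND

#' Build a rectangular graphene sheet
#'
#' Planar honeycomb lattice in the z = 0 plane, trimmed to the requested
#' rectangle. With `orientation = "armchair"` the armchair edge runs along
#' the x axis (the sheet's width); `"zigzag"` swaps the two axes.
#' All atoms are carbon with standard mass assigned.
#'
#' @param width,height sheet size in nm.
#' @param orientation `"armchair"` (default) or `"zigzag"`.
#' @return a [mol_structure()] labelled `"graphene"`.
#' @export
build_graphene <- function(width, height, orientation = c("armchair", "zigzag")) {
  orientation <- match.arg(orientation)
  if (width <= 0 || height <= 0) stop("width and height must be > 0")
  w <- width * 10; h <- height * 10  # nm -> A
  a <- .CC_BOND
  # rectangular 4-atom cell, armchair direction along x:
  # period 3a along x, sqrt(3) a along y
  dx <- 3 * a; dy <- sqrt(3) * a
  basis <- rbind(
    c(0, 0), c(a, 0),
    c(1.5 * a, sqrt(3) / 2 * a), c(2.5 * a, sqrt(3) / 2 * a)
  )
  if (w < 2 * a || h < dy) stop("requested rectangle is smaller than one hexagon")
  nx <- ceiling(w / dx) + 1; ny <- ceiling(h / dy) + 1
  cells <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1))
  pts <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b) {
    cbind(cells$ix * dx + basis[b, 1], cells$iy * dy + basis[b, 2])
  }))
  keep <- pts[, 1] <= w + 1e-9 & pts[, 2] <= h + 1e-9
  pts <- pts[keep, , drop = FALSE]
  pts <- pts[order(pts[, 2], pts[, 1]), , drop = FALSE]
  if (orientation == "zigzag") pts <- pts[, c(2, 1)]
  n <- nrow(pts)
  atoms <- data.frame(
    element = "C", atom_name = "C", chain_id = "G",
    residue_id = 1L, x = pts[, 1], y = pts[, 2], z = 0,
    stringsAsFactors = FALSE
  )
  assign_masses(mol_structure(atoms, label = "graphene"))
}

#' Carbon nanotube diameter from chiral indices
#'
#' Closed-form roll-up diameter d = (a / pi) * sqrt(n^2 + n m + m^2)
#' with lattice constant a = 2.46 A.
#'
#' @param n,m chiral indices, n >= m >= 0, n > 0.
#' @return diameter in angstrom.
#' @export
cnt_diameter <- function(n, m) {
  .LATTICE_A / pi * sqrt(n^2 + n * m + m^2)
}

#' Build a single-walled carbon nanotube from chiral indices
#'
#' Standard roll-up construction: the graphene lattice is mapped onto a
#' cylinder whose circumference is the chiral vector
#' `Ch = n a1 + m a2`, using arc-length mapping (the 1.42 A bond length
#' is preserved along the curved surface, so chord distances are slightly
#' shorter). Tube axis is z, starting at z = 0.
#'
#' @param n,m chiral indices with `n >= m >= 0`, `n > 0`.
#' @param length tube length in nm.
#' @return a [mol_structure()] labelled `"CNT(n,m)"`, carbon only,
#'   masses assigned.
#' @export
build_cnt <- function(n, m, length) {
  if (!(n >= m && m >= 0 && n > 0)) stop("invalid chiral indices: need n >= m >= 0, n > 0")
  if (length <= 0) stop("length must be > 0")
  L <- length * 10  # nm -> A
  a <- .LATTICE_A
  a1 <- c(a, 0); a2 <- c(a / 2, a * sqrt(3) / 2)
  ch <- n * a1 + m * a2
  C_len <- sqrt(sum(ch^2))
  radius <- C_len / (2 * pi)
  ch_hat <- ch / C_len
  t_hat <- c(-ch_hat[2], ch_hat[1])  # axis direction in the flat sheet
  # carbon basis within the (a1, a2) cell
  basis <- rbind(c(0, 0), (a1 + a2) / 3)
  # enumerate enough lattice cells to cover the [0, C_len) x [0, L) strip
  reach <- ceiling((C_len + L + 4 * a) / (a / 2))
  ij <- expand.grid(i = -reach:reach, j = -reach:reach)
  pos0 <- cbind(ij$i * a1[1] + ij$j * a2[1], ij$i * a1[2] + ij$j * a2[2])
  pts <- rbind(pos0, sweep(pos0, 2, -basis[2, ]))
  u <- pts %*% ch_hat          # coordinate along the circumference
  v <- pts %*% t_hat           # coordinate along the tube axis
  eps <- 1e-6
  keep <- u >= -eps & u < C_len - eps & v >= -eps & v < L - eps
  u <- u[keep]; v <- v[keep]
  if (!any(keep)) stop("tube too short to contain any atoms")
  theta <- 2 * pi * u / C_len
  xyz <- cbind(radius * cos(theta), radius * sin(theta), v)
  ord <- order(round(v, 6), round(theta, 6))
  xyz <- xyz[ord, , drop = FALSE]
  atoms <- data.frame(
    element = "C", atom_name = "C", chain_id = "T",
    residue_id = 1L, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  assign_masses(mol_structure(atoms, label = sprintf("CNT(%d,%d)", n, m)))
}
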