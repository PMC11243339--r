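# Normal-mode analysis of the mass-weighted ENM Hessian.
#
# Internal frequency unit: sqrt(kcal mol^-1 A^-2 amu^-1). The cm^-1
# conversion below is derived by unit analysis (energy per molecule /
# (length^2 * mass), square root, divided by 2*pi*c) and verified
# against an SI hand computation of the diatomic in the test suite.

.KCALMOL_J <- 4184 / 6.02214076e23       # J per (kcal/mol), per molecule
.AMU_KG <- 1.66053906660e-27
.C_CM_S <- 2.99792458e10

#' Conversion factor: internal frequency unit to cm^-1
#'
#' Multiply an internal-unit angular frequency
#' (sqrt(kcal mol^-1 A^-2 amu^-1)) by this to get a spectroscopic
#' wavenumber in cm^-1.
#' @export
freq_unit_to_cm1 <- function() {
  sqrt(.KCALMOL_J / (1e-20 * .AMU_KG)) / (2 * pi * .C_CM_S)
}

# Orthonormal basis of rigid-body motions in mass-weighted coordinates:
# sqrt(m) * translations and sqrt(m) * (omega x (r - com)). Rank 5 for
# collinear structures (rotation about the line is the zero vector).
.rigid_basis <- function(xyz, masses) {
  n <- nrow(xyz)
  sm <- sqrt(masses)
  com <- colSums(xyz * masses) / sum(masses)
  rc <- sweep(xyz, 2, com)
  V <- matrix(0, 3 * n, 6)
  for (a in 1:3) V[seq(a, 3 * n, by = 3), a] <- sm
  V[, 4] <- as.numeric(t(cbind(0, -rc[, 3], rc[, 2]) * sm))
  V[, 5] <- as.numeric(t(cbind(rc[, 3], 0, -rc[, 1]) * sm))
  V[, 6] <- as.numeric(t(cbind(-rc[, 2], rc[, 1], 0) * sm))
  qr_v <- qr(V)
  rdiag <- abs(diag(qr.R(qr_v)))
  rank <- sum(rdiag > 1e-7 * max(rdiag))
  qr.Q(qr_v)[, seq_len(rank), drop = FALSE]
}

.fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    mx <- which.max(abs(V[, k]))
    if (V[mx, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Solve for normal modes of a mass-weighted Hessian
#'
#' Returns the lowest `n_modes` eigenpairs of `H'`, sorted ascending.
#' Frequencies are `omega_k = sqrt(max(lambda_k, 0))` in the internal
#' unit (see [freq_unit_to_cm1()]). Rigid-body modes (6 for a
#' non-collinear isolated network, 5 for a collinear one, 0 with
#' anchored atoms) are flagged by an eigenvalue threshold relative to
#' the largest eigenvalue and cross-checked by projection onto the
#' analytically constructed translation/rotation vectors.
#'
#' Two solver paths: a dense `eigen()` for small systems, and for large
#' ones an ARPACK Lanczos run on `H'` with the analytic rigid modes
#' deflated by a Gershgorin-bound low-rank shift, which needs only
#' matrix-vector products (no factorisation). The paths agree on
#' overlapping sizes (tested).
#'
#' @param hprime a mass-weighted [assemble_hessian()] result (see
#'   [mass_weight()]).
#' @param n_modes number of lowest modes to return (including rigid
#'   ones); default 20 or 3N, whichever is smaller.
#' @param method `"auto"` (dense below `dense_atom_threshold` atoms),
#'   `"dense"` or `"sparse"`.
#' @param rigid_tol relative eigenvalue threshold for rigid-mode
#'   detection.
#' @param dense_atom_threshold atom count below which the dense path is
#'   used under `"auto"`.
#' @param arpack_tol ARPACK convergence tolerance.
#' @return an object of class `normal_modes`: `eigenvalues`,
#'   `frequencies`, `frequencies_cm1`, matrix `vectors` (3N x k,
#'   mass-weighted orthonormal columns, sign fixed so the
#'   largest-magnitude component is positive), logical `rigid`, and a
#'   list of `degenerate_groups`.
#' @export
solve_modes <- function(hprime, n_modes = NULL, method = c("auto", "dense", "sparse"),
                        rigid_tol = 1e-8, dense_atom_threshold = 300,
                        arpack_tol = 1e-9) {
  method <- match.arg(method)
  if (!inherits(hprime, "enm_hessian")) stop("hprime must be an enm_hessian")
  if (!hprime$mass_weighted) {
    warning("Hessian is not mass-weighted; frequencies assume unit masses")
  }
  N3 <- nrow(hprime$H)
  n_free <- N3 / 3
  if (is.null(n_modes)) n_modes <- min(20L, N3)
  if (n_modes > N3) stop("n_modes exceeds 3N = ", N3)
  anchored <- length(hprime$params$fixed) > 0
  use_dense <- method == "dense" || (method == "auto" && n_free <= dense_atom_threshold)

  xyz_free <- coords(hprime$structure)[hprime$free_atoms, , drop = FALSE]
  Vr <- if (!anchored) .rigid_basis(xyz_free, hprime$masses) else NULL
  n_rigid_expected <- if (anchored) 0L else ncol(Vr)

  if (use_dense) {
    eg <- eigen(as.matrix(hprime$H), symmetric = TRUE)
    ord <- order(eg$values)
    lambda_max <- max(eg$values)
    lam <- eg$values[ord][seq_len(n_modes)]
    V <- eg$vectors[, ord, drop = FALSE][, seq_len(n_modes), drop = FALSE]
  } else {
    gersh <- max(Matrix::rowSums(abs(hprime$H)))
    lambda_max <- gersh  # upper bound, used only to scale rigid_tol
    nev <- n_modes - n_rigid_expected
    if (nev < 1) stop("n_modes must exceed the number of rigid modes on the sparse path")
    H <- hprime$H
    beta <- 2 * gersh
    mult <- if (anchored) {
      function(x, extra) as.numeric(H %*% x)
    } else {
      function(x, extra) as.numeric(H %*% x) + beta * as.numeric(Vr %*% crossprod(Vr, x))
    }
    opts <- igraph::arpack_defaults
    if (is.function(opts)) opts <- opts()
    opts$n <- N3; opts$nev <- nev
    opts$ncv <- min(N3, max(60L, 6L * nev))
    opts$which <- "SA"; opts$maxiter <- 100000L; opts$tol <- arpack_tol
    res <- tryCatch(igraph::arpack(mult, options = opts, sym = TRUE),
                    error = function(e) stop("sparse eigensolver failed: ",
                                             conditionMessage(e)))
    ordr <- order(res$values)
    lam_nr <- res$values[ordr]
    V_nr <- res$vectors[, ordr, drop = FALSE]
    if (!anchored) {
      lam <- c(rep(0, n_rigid_expected), lam_nr)
      V <- cbind(Vr, V_nr)
    } else {
      lam <- lam_nr; V <- V_nr
    }
  }

  V <- .fix_signs(V)
  rigid <- lam < rigid_tol * lambda_max
  if (!anchored && !use_dense) rigid[seq_len(n_rigid_expected)] <- TRUE
  if (sum(rigid) != n_rigid_expected && use_dense) {
    # cross-check against analytic rigid space before complaining
    flagged <- which(rigid)
    if (!is.null(Vr) && length(flagged)) {
      proj <- sqrt(colSums(crossprod(Vr, V[, flagged, drop = FALSE])^2))
      if (any(proj < 0.99)) {
        warning("rigid-mode threshold and analytic rigid-space projection disagree")
      }
    }
    if (sum(rigid) != n_rigid_expected) {
      warning(sprintf("expected %d rigid modes, found %d below threshold",
                      n_rigid_expected, sum(rigid)))
    }
  }
  omega <- sqrt(pmax(lam, 0))
  groups <- .degenerate_groups(lam)
  out <- list(
    eigenvalues = lam,
    frequencies = omega,
    frequencies_cm1 = omega * freq_unit_to_cm1(),
    vectors = V,
    rigid = rigid,
    degenerate_groups = groups,
    n_atoms = n_free,
    free_atoms = hprime$free_atoms,
    structure = hprime$structure,
    params = hprime$params,
    lambda_max = lambda_max,
    solver = if (use_dense) "dense" else "sparse"
  )
  class(out) <- "normal_modes"
  out
}

.degenerate_groups <- function(lam, tol = 1e-10) {
  if (!length(lam)) return(list())
  scale <- max(abs(lam), 1e-300)
  grp <- cumsum(c(TRUE, diff(lam) > tol * scale))
  unname(split(seq_along(lam), grp))
}

#' @export
print.normal_modes <- function(x, ...) {
  nr <- sum(x$rigid)
  cat("normal_modes: ", length(x$eigenvalues), " modes (", nr, " rigid), ",
      x$solver, " solver\n", sep = "")
  nonr <- which(!x$rigid)
  if (length(nonr)) {
    cat("  first non-rigid frequencies (internal units): ",
        paste(signif(x$frequencies[utils::head(nonr, 5)], 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Non-rigid frequencies of a mode set
#'
#' @param modes a [solve_modes()] result.
#' @param k number of non-rigid modes wanted.
#' @param unit `"internal"` or `"cm-1"`.
#' @export
nonrigid_frequencies <- function(modes, k = NULL, unit = c("internal", "cm-1")) {
  unit <- match.arg(unit)
  f <- if (unit == "internal") modes$frequencies else modes$frequencies_cm1
  f <- f[!modes$rigid]
  if (!is.null(k)) {
    if (k > length(f)) stop("only ", length(f), " non-rigid modes available")
    f <- f[seq_len(k)]
  }
  f
}

#' Overlap matrix between two mode sets
#'
#' Absolute inner products `|<v_p, w_q>|` between mode vectors
#' restricted to a shared atom subset (the caller maps indices via
#' `atoms_a` / `atoms_b`, parallel vectors of equal length), each
#' restricted vector renormalised. All entries lie in [0, 1].
#'
#' @param a,b [solve_modes()] results.
#' @param k_modes number of leading modes (after dropping rigid ones)
#'   to compare.
#' @param atoms_a,atoms_b parallel atom index vectors into each set's
#'   free-atom list; default: all atoms (counts must then match).
#' @param drop_rigid drop rigid modes before comparing (default TRUE).
#' @return k x k matrix of absolute overlaps.
#' @export
mode_overlap <- function(a, b, k_modes, atoms_a = NULL, atoms_b = NULL,
                         drop_rigid = TRUE) {
  if (is.null(atoms_a)) atoms_a <- seq_len(a$n_atoms)
  if (is.null(atoms_b)) atoms_b <- seq_len(b$n_atoms)
  if (length(atoms_a) != length(atoms_b)) stop("atom maps must have equal length")
  if (length(atoms_a) == 0) stop("shared atom subset is empty")
  sel_a <- as.numeric(t(outer(3 * (atoms_a - 1), 1:3, "+")))
  sel_b <- as.numeric(t(outer(3 * (atoms_b - 1), 1:3, "+")))
  Va <- a$vectors[, if (drop_rigid) !a$rigid else TRUE, drop = FALSE]
  Vb <- b$vectors[, if (drop_rigid) !b$rigid else TRUE, drop = FALSE]
  if (k_modes > ncol(Va) || k_modes > ncol(Vb)) {
    stop("k_modes exceeds available modes")
  }
  Va <- Va[sel_a, seq_len(k_modes), drop = FALSE]
  Vb <- Vb[sel_b, seq_len(k_modes), drop = FALSE]
  Va <- sweep(Va, 2, sqrt(colSums(Va^2)), "/")
  Vb <- sweep(Vb, 2, sqrt(colSums(Vb^2)), "/")
  abs(crossprod(Va, Vb))
}

#' Apply a rotation to mode vectors
#'
#' When a structure is rigidly rotated by R, its ENM eigenvectors rotate
#' atom-block-wise by the same R. This helper maps mode vectors into the
#' rotated frame so they can be compared with modes recomputed there.
#'
#' @param modes a [solve_modes()] result.
#' @param R 3 x 3 rotation matrix.
#' @return the mode set with rotated vectors.
#' @export
rotate_mode_vectors <- function(modes, R) {
  V <- modes$vectors
  n <- modes$n_atoms
  for (k in seq_len(ncol(V))) {
    M <- matrix(V[, k], ncol = 3, byrow = TRUE)
    V[, k] <- as.numeric(t(M %*% t(R)))
  }
  modes$vectors <- .fix_signs(V)
  modes
}

#' Per-mode frequency comparison across two conditions
#'
#' Tabulates the first `k_modes` non-rigid frequencies of two mode sets
#' (e.g. enzyme in bulk vs. immobilized on a surface) and their ratios.
#' Which condition is stiffer is data-dependent; when condition b is
#' condition a plus extra springs on the same atom set, eigenvalue
#' monotonicity guarantees every ratio >= 1.
#'
#' @param a,b [solve_modes()] results computed with identical ENM
#'   parameters.
#' @param k_modes number of non-rigid modes to tabulate.
#' @return data frame with columns `mode`, `freq_a`, `freq_b`, `ratio`
#'   (= freq_b / freq_a), internal units.
#' @export
compare_frequencies <- function(a, b, k_modes = 3) {
  fa <- nonrigid_frequencies(a, k_modes)
  fb <- nonrigid_frequencies(b, k_modes)
  data.frame(mode = seq_len(k_modes), freq_a = fa, freq_b = fb,
             ratio = fb / fa)
}

#' Write modes in NMD plain-text format
#'
#' The NMD format (as used by normal-mode viewers for drawing modal
#' arrows): atom names, coordinates, then one `mode` line per mode with
#' its index, frequency and the 3N vector components.
#'
#' @param modes a [solve_modes()] result.
#' @param path output path.
#' @param n_modes how many non-rigid modes to write (default all
#'   available).
#' @export
write_nmd <- function(modes, path, n_modes = NULL) {
  nonr <- which(!modes$rigid)
  if (is.null(n_modes)) n_modes <- length(nonr)
  if (n_modes > length(nonr)) stop("only ", length(nonr), " non-rigid modes available")
  s <- modes$structure
  at <- s$atoms[modes$free_atoms, , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("title", s$label), con)
  writeLines(paste("names", paste(at$atom_name, collapse = " ")), con)
  writeLines(paste("resids", paste(at$residue_id, collapse = " ")), con)
  writeLines(paste("coordinates", paste(sprintf("%.3f", t(xyz)), collapse = " ")), con)
  for (q in seq_len(n_modes)) {
    k <- nonr[q]
    writeLines(paste("mode", q, sprintf("%.6g", modes$frequencies[k]),
                     paste(sprintf("%.6f", modes$vectors[, k]), collapse = " ")), con)
  }
  invisible(path)
}
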