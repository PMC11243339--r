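# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: brute-force double loops, central
# finite differences of an independently written energy, and an
# exhaustive rotation-grid search.

# O(N^2) pair list below a cutoff (strict inequality, i < j).
brute_force_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- list(); m <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r < cutoff) { m <- m + 1; out[[m]] <- c(i, j, r) }
  }
  if (m == 0) return(data.frame(i = integer(0), j = integer(0), r = numeric(0)))
  mm <- do.call(rbind, out)
  data.frame(i = as.integer(mm[, 1]), j = as.integer(mm[, 2]), r = mm[, 3])
}

# Independently coded distance-weighted spring stiffness with cubic
# smoothstep cutoff (same model, separate implementation).
oracle_spring_k <- function(r, k0 = 100, r0 = 5, ss = 10, rc = 12) {
  base <- k0 * exp(1 - (r / r0)^2)
  if (r >= rc) return(0)
  if (r <= ss) return(base)
  t <- (r - ss) / (rc - ss)
  base * (1 - t^2 * (3 - 2 * t))
}

# ENM potential energy from scratch (brute-force pair loop), and its
# central-finite-difference Hessian.
oracle_energy <- function(x_flat, ref_xyz, k0 = 100, r0 = 5, ss = 10, rc = 12) {
  n <- nrow(ref_xyz)
  xyz <- matrix(x_flat, ncol = 3, byrow = TRUE)
  E <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rref <- sqrt(sum((ref_xyz[i, ] - ref_xyz[j, ])^2))
    if (rref >= rc) next
    k <- oracle_spring_k(rref, k0, r0, ss, rc)
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    E <- E + 0.5 * k * (r - rref)^2
  }
  E
}

fd_hessian <- function(ref_xyz, h = 1e-5, ...) {
  x0 <- as.numeric(t(ref_xyz))
  n3 <- length(x0)
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) for (b in a:n3) {
    xpp <- x0; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
    xpm <- x0; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
    xmp <- x0; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
    xmm <- x0; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
    H[a, b] <- H[b, a] <- (oracle_energy(xpp, ref_xyz, ...) -
                             oracle_energy(xpm, ref_xyz, ...) -
                             oracle_energy(xmp, ref_xyz, ...) +
                             oracle_energy(xmm, ref_xyz, ...)) / (4 * h * h)
  }
  H
}

# Exhaustive rotation-grid minimum RMSD (proper rotations via Euler
# angles); independent check of the Kabsch solution.
grid_min_rmsd <- function(ref, mobile, step_deg = 6) {
  cr <- colMeans(ref); cm <- colMeans(mobile)
  X <- sweep(ref, 2, cr); Y <- sweep(mobile, 2, cm)
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  ang2 <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a in ang) for (b in ang2) for (g in ang) {
    Rz1 <- rotation_matrix(c(0, 0, 1), a)
    Ry <- rotation_matrix(c(0, 1, 0), b)
    Rz2 <- rotation_matrix(c(0, 0, 1), g)
    R <- Rz1 %*% Ry %*% Rz2
    v <- sqrt(mean(rowSums((Y %*% t(R) - X)^2)))
    if (v < best) best <- v
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  axis <- rnorm(3)
  rotation_matrix(axis, runif(1, 0.3, 2 * pi - 0.3))
}
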