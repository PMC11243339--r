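# Synthetic generators: toy structures, GOx-dimer-like globules, and
# rigid-motion-plus-noise trajectories with known displacement statistics.
# Every generator is a pure function of its arguments and seed (R's
# default Mersenne-Twister RNG); the caller's RNG state is left intact.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Two-atom oracle structure
#'
#' Two atoms on the x axis separated by exactly `d`, with explicit
#' masses. The one-spring system has the closed-form vibrational
#' frequency `omega = sqrt(k * (1/m1 + 1/m2))`, which makes this the
#' canonical fixture for the eigensolver.
#'
#' @param d separation in angstrom (> 0).
#' @param m1,m2 masses in amu (> 0).
#' @return a [mol_structure()] with two atoms at (0,0,0) and (d,0,0).
#' @export
make_two_body <- function(d, m1 = 12.011, m2 = 12.011) {
  if (d <= 0) stop("separation d must be > 0")
  if (m1 <= 0 || m2 <= 0) stop("masses must be > 0")
  atoms <- data.frame(
    element = "C", atom_name = c("C1", "C2"), chain_id = "A",
    residue_id = 1:2, x = c(0, d), y = 0, z = 0, mass = c(m1, m2),
    stringsAsFactors = FALSE
  )
  mol_structure(atoms, label = "two_body")
}

#' Collinear chain structure
#'
#' `n` equally spaced atoms on the x axis; a collinear fixture has 5
#' rigid-body modes instead of 6.
#'
#' @param n number of atoms (>= 2).
#' @param spacing spacing in angstrom.
#' @param mass amu per atom.
#' @export
make_linear_chain <- function(n, spacing = 3, mass = 12.011) {
  if (n < 2) stop("need at least 2 atoms")
  if (spacing <= 0) stop("spacing must be > 0")
  atoms <- data.frame(
    element = "C", atom_name = "C", chain_id = "A",
    residue_id = seq_len(n), x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    mass = mass, stringsAsFactors = FALSE
  )
  mol_structure(atoms, label = "linear_chain")
}

#' Random compact globule (enzyme-dimer stand-in)
#'
#' Atoms sampled uniformly in a sphere with a minimum pair separation
#' enforced by rejection (cell-grid accelerated), emulating the compact
#' heavy-atom cloud of a globular dimeric enzyme. The first half of the
#' atoms is labelled chain A, the second chain B. Deterministic per seed.
#'
#' @param n_atoms number of atoms (>= 4).
#' @param radius sphere radius in angstrom.
#' @param seed RNG seed.
#' @param min_sep minimum pair separation in angstrom (default 1.0,
#'   keeping the spring geometry non-degenerate).
#' @param element element symbol for all atoms.
#' @param max_tries total rejection budget; exceeded -> error.
#' @return a [mol_structure()] with masses assigned.
#' @export
make_random_globule <- function(n_atoms, radius, seed = 1, min_sep = 1.0,
                                element = "C", max_tries = 200 * n_atoms) {
  if (n_atoms < 4) stop("n_atoms must be >= 4")
  if (radius <= 0 || min_sep <= 0) stop("radius and min_sep must be > 0")
  pts <- .with_seed(seed, {
    out <- matrix(NA_real_, n_atoms, 3)
    grid <- new.env(hash = TRUE)
    h <- min_sep
    accepted <- 0; tries <- 0
    while (accepted < n_atoms) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("could not place ", n_atoms, " atoms with min_sep ", min_sep,
             " in radius ", radius, " after ", max_tries, " tries")
      }
      u <- stats::rnorm(3)
      p <- u / sqrt(sum(u^2)) * radius * stats::runif(1)^(1 / 3)
      ci <- floor(p / h)
      ok <- TRUE
      for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
        key <- paste(ci[1] + ox, ci[2] + oy, ci[3] + oz)
        occ <- grid[[key]]
        if (!is.null(occ)) {
          d2 <- colSums((t(out[occ, , drop = FALSE]) - p)^2)
          if (any(d2 < min_sep^2)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      accepted <- accepted + 1
      out[accepted, ] <- p
      key <- paste(ci[1], ci[2], ci[3])
      grid[[key]] <- c(grid[[key]], accepted)
    }
    out
  })
  chain <- rep(c("A", "B"), c(ceiling(n_atoms / 2), floor(n_atoms / 2)))
  atoms <- data.frame(
    element = element, atom_name = element, chain_id = chain,
    residue_id = seq_len(n_atoms), x = pts[, 1], y = pts[, 2], z = pts[, 3],
    stringsAsFactors = FALSE
  )
  assign_masses(mol_structure(atoms, label = "globule"))
}

#' Rotation matrix about an axis
#'
#' @param axis 3-vector (normalised internally).
#' @param angle angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Trajectory frame container
#'
#' @param coords array n_atoms x 3 x n_frames (angstrom).
#' @param times_ps strictly increasing timestamps in ps.
#' @param structure the base [mol_structure()] the frames refer to.
#' @export
trajectory_frames <- function(coords, times_ps, structure = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3,
            dim(coords)[3] == length(times_ps))
  if (length(times_ps) > 1 && any(diff(times_ps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  out <- list(coords = coords, times_ps = times_ps, structure = structure)
  class(out) <- "trajectory_frames"
  out
}

#' @export
print.trajectory_frames <- function(x, ...) {
  d <- dim(x$coords)
  cat("trajectory_frames:", d[3], "frames x", d[1], "atoms,",
      "t =", x$times_ps[1], "..", x$times_ps[d[3]], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory_frames`
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Synthetic rigid-motion + Gaussian-noise trajectory
#'
#' Frame k (k = 0, ..., n_frames-1) is the base structure rotated by
#' `k * angle_per_frame` about `axis` through the base centroid,
#' translated by `k * translation_per_frame`, plus isotropic Gaussian
#' noise of standard deviation `noise_sigma` per coordinate, drawn
#' independently per atom, coordinate and frame. Frame 0 is the
#' reference configuration and is always emitted noise-free, so it
#' equals the base exactly under the identity motion. For large atom
#' counts the expected superposed RMSD of a noisy frame against the
#' base is `noise_sigma * sqrt(3)`.
#'
#' @param base a [mol_structure()].
#' @param n_frames number of frames (>= 1).
#' @param noise_sigma Gaussian noise sd per coordinate, angstrom.
#' @param axis rotation axis (default z).
#' @param angle_per_frame radians per frame.
#' @param translation_per_frame 3-vector, angstrom per frame.
#' @param timestep ps between frames (trajectories are recorded at 1 ps
#'   by default).
#' @param seed RNG seed.
#' @return a [trajectory_frames()].
#' @export
make_trajectory <- function(base, n_frames, noise_sigma = 0,
                            axis = c(0, 0, 1), angle_per_frame = 0,
                            translation_per_frame = c(0, 0, 0),
                            timestep = 1, seed = 1) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  x0 <- coords(base)
  n <- nrow(x0)
  ctr <- colMeans(x0)
  xc <- sweep(x0, 2, ctr)
  out <- array(NA_real_, c(n, 3, n_frames))
  .with_seed(seed, {
    for (k in seq_len(n_frames) - 1) {
      R <- rotation_matrix(axis, k * angle_per_frame)
      xk <- xc %*% t(R)
      xk <- sweep(xk, 2, ctr + k * translation_per_frame, "+")
      if (noise_sigma > 0 && k > 0) {
        xk <- xk + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
      }
      out[, , k + 1] <- xk
    }
  })
  trajectory_frames(out, times_ps = (seq_len(n_frames) - 1) * timestep, structure = base)
}

#' Write trajectory frames as a multi-frame XYZ file
#'
#' Plain whitespace-delimited XYZ, one block per frame; the comment line
#' carries the timestamp in ps.
#'
#' @param traj a [trajectory_frames()].
#' @param path output path.
#' @export
write_xyz_frames <- function(traj, path) {
  n <- dim(traj$coords)[1]
  el <- if (!is.null(traj$structure)) traj$structure$atoms$element else rep("C", n)
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n), sprintf("t= %.6g ps", traj$times_ps[k])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el,
                       traj$coords[, 1, k], traj$coords[, 2, k], traj$coords[, 3, k]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path path to a file written in the layout of
#'   [write_xyz_frames()].
#' @return a [trajectory_frames()] (timestamps parsed from the comment
#'   line when present, else 0, 1, 2, ... ps).
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); pos <- 1; k <- 0
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("bad XYZ atom count at line ", pos)
    cmt <- lines[pos + 1]
    tm <- regmatches(cmt, regexec("t= *([-0-9.eE+]+)", cmt))[[1]]
    k <- k + 1
    times[k] <- if (length(tm) == 2) as.numeric(tm[2]) else k - 1
    block <- lines[(pos + 2):(pos + 1 + n)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "[[:space:]]+"), function(f) {
      as.numeric(f[2:4])
    }))
    frames[[k]] <- m
    pos <- pos + 2 + n
  }
  arr <- array(NA_real_, c(nrow(frames[[1]]), 3, k))
  for (i in seq_len(k)) arr[, , i] <- frames[[i]]
  trajectory_frames(arr, times_ps = times)
}

#' Read a multi-model PDB as trajectory frames
#'
#' Each MODEL of the file becomes one frame (1 ps spacing by default).
#'
#' @param path PDB path.
#' @param timestep ps between models.
#' @export
read_trajectory_pdb <- function(path, timestep = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); n <- ncol(xyz) / 3
  arr <- array(NA_real_, c(n, 3, nf))
  for (k in seq_len(nf)) arr[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
  trajectory_frames(arr, times_ps = (seq_len(nf) - 1) * timestep)
}
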