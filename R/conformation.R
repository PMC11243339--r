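# Interface conformational statistics over trajectory frames:
# least-squares superposition (Kabsch), RMSD series, radius of gyration,
# enzyme-surface contact counts, minimum cross distance, and tail-window
# averaging. Coordinates are angstrom internally; the reporting
# functions return nm.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid fit of `mobile` onto `ref` (optionally
#' mass-weighted), with a proper rotation (det = +1) enforced.
#'
#' @param ref,mobile n x 3 coordinate matrices, equal atom counts
#'   (>= 3 non-collinear atoms for a unique rotation).
#' @param weights optional non-negative weights (e.g. masses).
#' @return list with `rotation` (3 x 3), `translation` (length 3, so
#'   that `fitted = mobile %*% t(rotation) + translation`), `rmsd`
#'   (weighted, same length unit as the input), and `fitted`.
#' @export
kabsch_superpose <- function(ref, mobile, weights = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (!all(dim(ref) == dim(mobile))) stop("coordinate sets differ in size")
  n <- nrow(ref)
  if (n < 1) stop("empty coordinate sets")
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w < 0) || sum(w) == 0) stop("bad weights")
  w <- w / sum(w)
  cr <- colSums(ref * w); cm <- colSums(mobile * w)
  X <- sweep(ref, 2, cr); Y <- sweep(mobile, 2, cm)
  C <- crossprod(Y * w, X)           # 3x3 covariance
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Y %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - X)^2)))
  fitted <- sweep(fitted, 2, cr, "+")
  list(rotation = R, translation = as.numeric(cr - (cm %*% t(R))),
       rmsd = rmsd, fitted = fitted)
}

#' Per-frame superposed RMSD series
#'
#' RMSD of each frame's masked atoms against a reference frame after
#' optimal superposition, in nm.
#'
#' @param traj a [trajectory_frames()].
#' @param ref_frame index of the reference frame (default 1).
#' @param mask integer atom indices to include (default all).
#' @param weights optional per-atom weights over the mask; defaults to
#'   the base structure's masses when available, else uniform.
#' @return numeric vector, one nm value per frame.
#' @export
rmsd_series <- function(traj, ref_frame = 1, mask = NULL, weights = NULL) {
  nf <- n_frames(traj)
  n <- dim(traj$coords)[1]
  if (is.null(mask)) mask <- seq_len(n)
  if (length(mask) == 0) stop("empty selection mask")
  if (any(mask < 1 | mask > n)) stop("mask indices out of range")
  if (ref_frame < 1 || ref_frame > nf) stop("ref_frame out of range")
  if (is.null(weights)) {
    weights <- if (!is.null(traj$structure) && !any(is.na(traj$structure$atoms$mass))) {
      traj$structure$atoms$mass[mask]
    } else rep(1, length(mask))
  }
  ref <- traj$coords[mask, , ref_frame]
  vapply(seq_len(nf), function(k) {
    kabsch_superpose(ref, traj$coords[mask, , k], weights = weights)$rmsd
  }, numeric(1)) / 10
}

#' Mass-weighted radius of gyration
#'
#' `Rg = sqrt( sum m_a |r_a - r_com|^2 / sum m_a )`, reported in nm.
#'
#' @param xyz n x 3 coordinate matrix in angstrom (or a
#'   [mol_structure()], in which case masses are taken from it).
#' @param masses per-atom masses in amu.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(xyz, masses = NULL) {
  if (inherits(xyz, "mol_structure")) {
    if (is.null(masses)) masses <- xyz$atoms$mass
    xyz <- coords(xyz)
  }
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n < 1) stop("need at least one atom")
  if (is.null(masses)) masses <- rep(1, n)
  if (any(is.na(masses))) stop("masses not assigned")
  if (sum(masses) <= 0) stop("total mass must be > 0")
  com <- colSums(xyz * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(xyz, 2, com)^2)) / sum(masses)) / 10
}

#' Count enzyme-surface contacts
#'
#' Number of cross pairs (one atom from each mask) closer than
#' `contact_cutoff`, computed with a cell grid (identical to the O(N^2)
#' double loop). `mode = "atoms"` instead counts the unique atoms (over
#' both masks) involved in at least one contact, since "number of
#' contact atoms" is ambiguous between the two conventions.
#'
#' @param a_mask,b_mask disjoint integer atom index vectors.
#' @param xyz n x 3 coordinates in angstrom.
#' @param contact_cutoff contact distance in angstrom (default 6.0).
#' @param mode `"pairs"` (default) or `"atoms"`.
#' @return integer count.
#' @export
count_contacts <- function(a_mask, b_mask, xyz, contact_cutoff = 6, mode = c("pairs", "atoms")) {
  mode <- match.arg(mode)
  if (length(intersect(a_mask, b_mask))) stop("selection masks overlap")
  if (!length(a_mask) || !length(b_mask)) stop("empty selection mask")
  xyz <- as.matrix(xyz)
  cp <- .cross_pairs(xyz[a_mask, , drop = FALSE], xyz[b_mask, , drop = FALSE],
                     contact_cutoff)
  if (mode == "pairs") nrow(cp)
  else length(unique(a_mask[cp$ia])) + length(unique(b_mask[cp$ib]))
}

#' Minimum distance between two selections
#'
#' Smallest Euclidean distance over all cross pairs, in nm. Uses the
#' cell grid with an expanding search radius, so the result equals the
#' brute-force minimum.
#'
#' @param a_mask,b_mask non-empty integer atom index vectors.
#' @param xyz n x 3 coordinates in angstrom.
#' @return minimum distance in nm.
#' @export
min_distance <- function(a_mask, b_mask, xyz) {
  if (!length(a_mask) || !length(b_mask)) stop("empty selection mask")
  xyz <- as.matrix(xyz)
  xa <- xyz[a_mask, , drop = FALSE]; xb <- xyz[b_mask, , drop = FALSE]
  # expanding-radius grid search; guaranteed exact once a hit is found
  # within the current radius (any closer pair would also be within it)
  span <- sqrt(sum((apply(rbind(xa, xb), 2, max) - apply(rbind(xa, xb), 2, min))^2))
  r <- max(span / 8, 1e-6)
  repeat {
    cp <- .cross_pairs(xa, xb, r)
    if (nrow(cp)) return(min(cp$r) / 10)
    if (r > span) {
      # disjoint clouds further apart than their joint span: fall back
      # to a direct block computation
      d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
      return(sqrt(max(min(d2), 0)) / 10)
    }
    r <- r * 2
  }
}

#' Average of a series over a trailing time window
#'
#' Arithmetic mean of the samples whose timestamp lies in
#' `(t_end - window, t_end]` (half-open, so a window of w ps covers
#' exactly the trailing w ps of samples at unit spacing).
#'
#' @param series numeric values.
#' @param timestamps matching timestamps in ps, strictly increasing.
#' @param window window length in ps; must not exceed the series
#'   duration.
#' @param anchor only `"tail"` is supported.
#' @return the mean over the window.
#' @export
window_average <- function(series, timestamps, window, anchor = "tail") {
  anchor <- match.arg(anchor, "tail")
  if (length(series) != length(timestamps)) stop("series/timestamps length mismatch")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  duration <- timestamps[length(timestamps)] - timestamps[1]
  if (window > duration) stop("window (", window, " ps) exceeds series duration (",
                              duration, " ps)")
  t_end <- timestamps[length(timestamps)]
  sel <- timestamps > t_end - window & timestamps <= t_end
  mean(series[sel])
}

#' Tidy interface statistics over a trajectory
#'
#' Convenience driver: per-frame RMSD (of the `enzyme_mask` selection),
#' radius of gyration, contact count and minimum distance between
#' enzyme and surface selections, in long format.
#'
#' @param traj a [trajectory_frames()].
#' @param enzyme_mask,surface_mask disjoint atom index vectors.
#' @param contact_cutoff contact cutoff in angstrom.
#' @param masses optional per-atom masses for Rg/RMSD weighting.
#' @return data frame with columns `frame`, `time_ps`, `metric`,
#'   `value` (rmsd_nm, rg_nm, contacts, min_dist_nm).
#' @export
interface_statistics <- function(traj, enzyme_mask, surface_mask,
                                 contact_cutoff = 6, masses = NULL) {
  nf <- n_frames(traj)
  if (is.null(masses) && !is.null(traj$structure) &&
      !any(is.na(traj$structure$atoms$mass))) {
    masses <- traj$structure$atoms$mass
  }
  rmsd <- rmsd_series(traj, mask = enzyme_mask,
                      weights = if (!is.null(masses)) masses[enzyme_mask])
  rows <- lapply(seq_len(nf), function(k) {
    xyz <- traj$coords[, , k]
    data.frame(
      frame = k, time_ps = traj$times_ps[k],
      metric = c("rmsd_nm", "rg_nm", "contacts", "min_dist_nm"),
      value = c(
        rmsd[k],
        radius_of_gyration(xyz[enzyme_mask, , drop = FALSE],
                           if (!is.null(masses)) masses[enzyme_mask]),
        count_contacts(enzyme_mask, surface_mask, xyz, contact_cutoff),
        min_distance(enzyme_mask, surface_mask, xyz)
      )
    )
  })
  do.call(rbind, rows)
}
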