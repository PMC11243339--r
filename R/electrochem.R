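# Scan-rate cyclic-voltammetry analysis for surface-confined redox
# couples (GOx-FAD-like): synthetic voltammogram/peak generation from a
# known apparent electron-transfer rate, peak extraction with linear
# baseline correction, and rate estimation by Laviron trumpet-plot
# regression. The generator and the estimator share one forward model,
# so zero-noise round trips are exact.
#
# Forward model (Laviron, surface-confined couple; v in V/s):
#   m_a = RT / ((1-alpha) n F),  m_c = RT / (alpha n F)
#   Epa = E0 + max(0, m_a * ln(v / v_a)),  v_a = RT ks / ((1-alpha) n F)
#   Epc = E0 - max(0, m_c * ln(v / v_c)),  v_c = RT ks / (alpha n F)
# i.e. peaks sit at the formal potential in the reversible (slow-scan)
# limit and fan out linearly in ln(v) beyond it.

.F_C <- 96485.33212     # C/mol
.R_J <- 8.314462618     # J/(mol K)

.laviron_slopes <- function(alpha, n_e, T) {
  list(m_a = .R_J * T / ((1 - alpha) * n_e * .F_C),
       m_c = .R_J * T / (alpha * n_e * .F_C))
}

#' Laviron peak potentials for a surface-confined couple
#'
#' @param scan_rate_Vs scan rate(s) in V/s.
#' @param ks apparent electron-transfer rate constant, 1/s.
#' @param alpha transfer coefficient in (0, 1).
#' @param n_e number of electrons.
#' @param T temperature in K.
#' @param E0 formal potential in V.
#' @return data frame with `Epa_V` and `Epc_V`.
#' @export
laviron_peaks <- function(scan_rate_Vs, ks, alpha = 0.5, n_e = 2, T = 298.15, E0 = 0.15) {
  if (ks <= 0) stop("ks must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  sl <- .laviron_slopes(alpha, n_e, T)
  v_a <- .R_J * T * ks / ((1 - alpha) * n_e * .F_C)
  v_c <- .R_J * T * ks / (alpha * n_e * .F_C)
  data.frame(
    Epa_V = E0 + pmax(0, sl$m_a * log(scan_rate_Vs / v_a)),
    Epc_V = E0 - pmax(0, sl$m_c * log(scan_rate_Vs / v_c))
  )
}

#' Synthetic scan-rate peak table from a known rate constant
#'
#' Generates anodic/cathodic peak potentials at the given scan rates
#' from the Laviron forward model, with optional Gaussian noise on the
#' peak potentials, plus surface-confined peak current densities
#' (i_p = n^2 F^2 v Gamma / (4 R T), anodic positive, cathodic
#' negative). With zero noise, [estimate_ks()] inverts the table
#' exactly.
#'
#' @param ks apparent rate constant, 1/s.
#' @param alpha transfer coefficient.
#' @param n_e electrons transferred.
#' @param T temperature, K.
#' @param scan_rates scan rates in mV/s (default: the 10-120 mV/s
#'   series used throughout).
#' @param peak_noise sd of Gaussian noise added to each peak potential,
#'   mV.
#' @param E0 formal potential, V.
#' @param Gamma surface coverage, mol/cm^2 (only affects currents).
#' @param seed RNG seed.
#' @return data frame (`scan_rate_mV_s`, `Epa_V`, `Epc_V`, `ipa_A_cm2`,
#'   `ipc_A_cm2`) of class `peak_table`.
#' @export
make_synthetic_cv <- function(ks, alpha = 0.5, n_e = 2, T = 298.15,
                              scan_rates = c(10, 20, 35, 50, 65, 80, 100, 120),
                              peak_noise = 0, E0 = 0.15, Gamma = 1e-10, seed = 1) {
  if (!length(scan_rates)) stop("scan-rate list is empty")
  if (any(scan_rates <= 0)) stop("scan rates must be > 0")
  if (anyDuplicated(scan_rates)) stop("scan rates must be unique")
  v <- scan_rates / 1000
  pk <- laviron_peaks(v, ks, alpha, n_e, T, E0)
  if (peak_noise > 0) {
    noise <- .with_seed(seed, matrix(stats::rnorm(2 * length(v), sd = peak_noise / 1000),
                                     ncol = 2))
    pk$Epa_V <- pk$Epa_V + noise[, 1]
    pk$Epc_V <- pk$Epc_V + noise[, 2]
  }
  ip <- n_e^2 * .F_C^2 * v * Gamma / (4 * .R_J * T)
  out <- data.frame(scan_rate_mV_s = scan_rates, Epa_V = pk$Epa_V, Epc_V = pk$Epc_V,
                    ipa_A_cm2 = ip, ipc_A_cm2 = -ip)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Synthetic full voltammogram trace
#'
#' A two-branch potential sweep with Gaussian redox waves centred at
#' the Laviron peak potentials on a linear capacitive baseline; input
#' for [extract_peaks()] in tests and demonstrations.
#'
#' @inheritParams make_synthetic_cv
#' @param scan_rate single scan rate, mV/s.
#' @param E_range sweep limits in V (default -0.3 to 0.6).
#' @param E_step potential step in V (default 0.010, i.e. 10 mV).
#' @param peak_width Gaussian peak width (sd), V.
#' @param baseline_slope capacitive baseline slope, A/cm^2 per V.
#' @param baseline_offset baseline offset, A/cm^2.
#' @return data frame (`potential_V`, `current_A_cm2`) with attribute
#'   `scan_rate_mV_s`; forward (anodic-going) branch first.
#' @export
make_cv_trace <- function(ks, scan_rate, alpha = 0.5, n_e = 2, T = 298.15,
                          E0 = 0.15, E_range = c(-0.3, 0.6), E_step = 0.010,
                          peak_width = 0.05, Gamma = 1e-10,
                          baseline_slope = 1e-6, baseline_offset = 0) {
  v <- scan_rate / 1000
  pk <- laviron_peaks(v, ks, alpha, n_e, T, E0)
  ip <- n_e^2 * .F_C^2 * v * Gamma / (4 * .R_J * T)
  fwd <- seq(E_range[1], E_range[2], by = E_step)
  rev <- seq(E_range[2], E_range[1], by = -E_step)
  i_fwd <- ip * exp(-(fwd - pk$Epa_V)^2 / (2 * peak_width^2)) +
    baseline_slope * fwd + baseline_offset
  i_rev <- -ip * exp(-(rev - pk$Epc_V)^2 / (2 * peak_width^2)) +
    baseline_slope * rev + baseline_offset
  out <- data.frame(potential_V = c(fwd, rev), current_A_cm2 = c(i_fwd, i_rev))
  attr(out, "scan_rate_mV_s") <- scan_rate
  out
}

#' Extract redox peaks from one voltammogram
#'
#' Splits the sweep into forward and reverse branches at the potential
#' turning point, fits a linear baseline to the leading fraction of each
#' branch, and takes the anodic peak as the maximum of the
#' baseline-corrected forward branch and the cathodic peak as the
#' minimum of the corrected reverse branch. A peak must be an interior
#' extremum exceeding `noise_mult` times the baseline residual sd,
#' otherwise a "no peak" error is raised.
#'
#' @param v data frame with columns `potential_V` and `current_A_cm2`
#'   (both sweep branches, forward first).
#' @param scan_rate scan rate in mV/s (taken from
#'   `attr(v, "scan_rate_mV_s")` when missing).
#' @param baseline_frac fraction of each branch used for the baseline
#'   fit (default 0.2).
#' @param noise_mult peak height threshold in baseline-residual sds.
#' @return one-row data frame (`scan_rate_mV_s`, `Epa_V`, `Epc_V`,
#'   `ipa_A_cm2`, `ipc_A_cm2`), currents baseline-corrected.
#' @export
extract_peaks <- function(v, scan_rate = NULL, baseline_frac = 0.2, noise_mult = 5) {
  if (is.null(scan_rate)) scan_rate <- attr(v, "scan_rate_mV_s")
  if (is.null(scan_rate)) stop("scan_rate not given and not attached to the trace")
  E <- v$potential_V; I <- v$current_A_cm2
  if (length(E) < 6) stop("trace too short")
  turn <- if (E[2] > E[1]) which.max(E) else which.min(E)
  if (turn < 3 || turn > length(E) - 2) stop("could not find both sweep branches")
  one_branch <- function(Eb, Ib, sign) {
    nb <- length(Eb)
    nb0 <- max(3, floor(baseline_frac * nb))
    fit <- stats::lm(Ib[seq_len(nb0)] ~ Eb[seq_len(nb0)])
    resid_sd <- stats::sd(stats::residuals(fit))
    corr <- Ib - (stats::coef(fit)[1] + stats::coef(fit)[2] * Eb)
    idx <- if (sign > 0) which.max(corr) else which.min(corr)
    height <- abs(corr[idx])
    floor_ <- noise_mult * max(resid_sd, 1e-15)
    if (idx <= 1 || idx >= nb || height < floor_) {
      stop("no peak found on the ", if (sign > 0) "anodic" else "cathodic", " branch")
    }
    list(E = Eb[idx], i = corr[idx])
  }
  an <- one_branch(E[1:turn], I[1:turn], +1)
  ca <- one_branch(E[(turn + 1):length(E)], I[(turn + 1):length(E)], -1)
  out <- data.frame(scan_rate_mV_s = scan_rate, Epa_V = an$E, Epc_V = ca$E,
                    ipa_A_cm2 = an$i, ipc_A_cm2 = ca$i)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Estimate the apparent electron-transfer rate constant
#'
#' Laviron trumpet-plot analysis: over the scan rates whose peak
#' separation is resolvable (`Epa - Epc > min_sep_V`), each branch's
#' peak potential is linear in ln(scan rate) with slope fixed by
#' `alpha`; the two branch intercepts give the formal potential and the
#' rate constant in closed form:
#' `ln ks = [(c_c - c_a) - m_c ln(RT/(alpha n F)) - m_a ln(RT/((1-alpha) n F))] / (m_a + m_c)`
#' where `c_a = mean(Epa - m_a ln v)` and `c_c = mean(Epc + m_c ln v)`.
#' Shares its forward model with [make_synthetic_cv()], so a zero-noise
#' table is inverted exactly.
#'
#' @param peaks a peak table (`scan_rate_mV_s`, `Epa_V`, `Epc_V`).
#' @param alpha transfer coefficient (default 0.5).
#' @param n_e electrons transferred (default 2).
#' @param T temperature, K.
#' @param min_sep_V resolvability threshold on the peak separation
#'   (default 0.010 V).
#' @return list of class `ks_estimate`: `ks` (1/s), `E0` (V),
#'   `n_used`, `residual_sd_V`, and the parameters used.
#' @export
estimate_ks <- function(peaks, alpha = 0.5, n_e = 2, T = 298.15, min_sep_V = 0.010) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nrow(peaks) < 3) stop("need peaks at >= 3 scan rates")
  if (anyDuplicated(peaks$scan_rate_mV_s)) stop("scan rates must be unique")
  sep <- peaks$Epa_V - peaks$Epc_V
  act <- sep > min_sep_V
  if (!any(act)) {
    stop("all peak separations below ", min_sep_V * 1000,
         " mV: reversible regime, ks not identifiable")
  }
  sl <- .laviron_slopes(alpha, n_e, T)
  solve_for <- function(act) {
    v <- peaks$scan_rate_mV_s[act] / 1000
    c_a <- mean(peaks$Epa_V[act] - sl$m_a * log(v))
    c_c <- mean(peaks$Epc_V[act] + sl$m_c * log(v))
    ln_ks <- ((c_c - c_a) -
                sl$m_c * log(.R_J * T / (alpha * n_e * .F_C)) -
                sl$m_a * log(.R_J * T / ((1 - alpha) * n_e * .F_C))) /
      (sl$m_a + sl$m_c)
    list(ks = exp(ln_ks),
         E0 = c_a + sl$m_a * (ln_ks + log(.R_J * T / ((1 - alpha) * n_e * .F_C))))
  }
  est <- solve_for(act)
  # refine: keep only rates where the fitted model predicts both
  # branches out of the reversible regime (matters for alpha far from
  # 0.5, where one branch lags the other)
  for (it in 1:3) {
    v_all <- peaks$scan_rate_mV_s / 1000
    v_a <- .R_J * T * est$ks / ((1 - alpha) * n_e * .F_C)
    v_c <- .R_J * T * est$ks / (alpha * n_e * .F_C)
    act_new <- act & v_all > v_a & v_all > v_c
    if (!any(act_new) || identical(act_new, act)) break
    act <- act_new
    est <- solve_for(act)
  }
  ks <- est$ks
  E0 <- est$E0
  v <- peaks$scan_rate_mV_s[act] / 1000
  pred <- laviron_peaks(v, ks, alpha, n_e, T, E0)
  resid <- c(peaks$Epa_V[act] - pred$Epa_V, peaks$Epc_V[act] - pred$Epc_V)
  out <- list(ks = ks, E0 = E0, n_used = sum(act),
              residual_sd_V = stats::sd(resid),
              alpha = alpha, n_e = n_e, T = T, min_sep_V = min_sep_V)
  class(out) <- "ks_estimate"
  out
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("ks = %.4g 1/s (E0 = %.4f V; %d scan rates used; residual sd %.2g V)\n",
              x$ks, x$E0, x$n_used, x$residual_sd_V))
  cat(sprintf("  alpha = %.2f, n = %d, T = %.2f K\n", x$alpha, x$n_e, x$T))
  invisible(x)
}

#' Fold change between two rate constants
#'
#' @param ks_test,ks_ref rate constants (1/s); `ks_ref` must be > 0.
#' @return `ks_test / ks_ref`.
#' @export
fold_change <- function(ks_test, ks_ref) {
  if (ks_ref <= 0) stop("reference rate constant must be > 0")
  ks_test / ks_ref
}
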