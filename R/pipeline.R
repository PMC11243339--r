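# End-to-end driver wiring the stages together: synthetic structures ->
# ENM normal modes (bulk vs. immobilized) -> trajectory interface
# statistics -> scan-rate CV rate estimation. Deterministic under
# config + seed; every output carries the full parameter set.

#' Pipeline configuration
#'
#' All tunable parameters with their defaults: the ENM parameters
#' default to the model's stated values (k0 = 100 kcal/(mol A^2),
#' r0 = 5 A, cutoff = 12 A) and everything else to documented package
#' defaults. Validation happens before any compute.
#'
#' @param k0,r0,switch_start,cutoff ENM parameters (kcal/(mol A^2), A).
#' @param n_modes number of modes to solve for.
#' @param globule_atoms,globule_radius synthetic enzyme-dimer stand-in
#'   size (atoms, A).
#' @param surface_nm graphene sheet edge length used for the
#'   immobilized condition, nm.
#' @param contact_cutoff contact distance, A.
#' @param traj_frames,traj_sigma trajectory generator settings (frames,
#'   A noise per coordinate).
#' @param tail_window_ps trailing averaging window, ps.
#' @param alpha,n_e,T_K,scan_rates,ks_values CV settings; `ks_values` is
#'   a named vector of rate constants (1/s) for the synthetic
#'   electrodes.
#' @param cv_peak_noise_mV peak potential noise, mV.
#' @param seed RNG seed for every stochastic stage.
#' @param outdir output directory.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(k0 = 100, r0 = 5, switch_start = 10, cutoff = 12,
                            n_modes = 9,
                            globule_atoms = 150, globule_radius = 9,
                            surface_nm = 2,
                            contact_cutoff = 6,
                            traj_frames = 30, traj_sigma = 0.2,
                            tail_window_ps = 10,
                            alpha = 0.5, n_e = 2, T_K = 298.15,
                            scan_rates = c(10, 20, 35, 50, 65, 80, 100, 120),
                            ks_values = c(cnt = 0.05, graphene = 0.0941, composite = 0.2305),
                            cv_peak_noise_mV = 0,
                            seed = 1, outdir = tempfile("enmox_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @return the config, invisibly; errors on the first invalid field.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config validation: ", msg, call. = FALSE)
  chk(cfg$k0 > 0, "k0 must be > 0")
  chk(cfg$r0 > 0, "r0 must be > 0")
  chk(cfg$switch_start < cfg$cutoff, "switch_start must be < cutoff")
  chk(cfg$cutoff > 0, "cutoff must be > 0")
  chk(cfg$globule_atoms >= 4, "globule_atoms must be >= 4")
  chk(cfg$contact_cutoff > 0, "contact_cutoff must be > 0")
  chk(cfg$traj_frames >= 1, "traj_frames must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  chk(length(cfg$scan_rates) >= 3, "need at least 3 scan rates")
  chk(all(cfg$ks_values > 0), "ks_values must be > 0")
  invisible(cfg)
}

.write_config_echo <- function(cfg, path) {
  flat <- lapply(cfg, function(x) paste(format(x, digits = 12), collapse = ", "))
  writeLines(c("# enmox pipeline configuration",
               sprintf("%s: %s", names(flat), unlist(flat))), path)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) build a graphene sheet and a synthetic globular dimer;
#' (2) ENM normal modes of the enzyme in bulk and immobilized on the
#' sheet (surface atoms as fixed anchors), with a frequency comparison
#' table; (3) a rigid-motion-plus-noise trajectory of the enzyme over
#' the sheet with interface statistics and tail averages; (4) synthetic
#' scan-rate CV peak tables per electrode with rate estimation and fold
#' changes. Deterministic for a fixed config; outputs are CSV files
#' under `cfg$outdir` plus a config echo for provenance.
#'
#' @param cfg a [pipeline_config()].
#' @return invisibly, a list with the key result tables
#'   (`frequencies`, `stats`, `tail_averages`, `rates`) and the output
#'   directory.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  .write_config_echo(cfg, file.path(cfg$outdir, "config.txt"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # -- structures ------------------------------------------------------
  built <- stage("structures", {
    sheet <- build_graphene(cfg$surface_nm, cfg$surface_nm, "armchair")
    enz <- make_random_globule(cfg$globule_atoms, cfg$globule_radius, seed = cfg$seed)
    # park the enzyme just above the sheet centre
    xyz <- coords(enz)
    shift <- c(cfg$surface_nm * 5, cfg$surface_nm * 5, 4 - min(xyz[, 3]))
    coords(enz) <- sweep(xyz, 2, shift, "+")
    write_pdb(sheet, file.path(cfg$outdir, "graphene.pdb"))
    write_pdb(enz, file.path(cfg$outdir, "enzyme.pdb"))
    list(sheet = sheet, enz = enz)
  })

  # -- normal modes: bulk vs immobilized -------------------------------
  freq_tab <- stage("modes", {
    net_bulk <- build_network(built$enz, cfg$k0, cfg$r0, cfg$switch_start, cfg$cutoff)
    modes_bulk <- solve_modes(mass_weight(assemble_hessian(net_bulk)),
                              n_modes = cfg$n_modes)
    comb <- combine_structures(built$enz, built$sheet, label = "enzyme+graphene")
    net_imm <- build_network(comb, cfg$k0, cfg$r0, cfg$switch_start, cfg$cutoff)
    fixed <- n_atoms(built$enz) + seq_len(n_atoms(built$sheet))
    modes_imm <- solve_modes(mass_weight(assemble_hessian(net_imm, fixed = fixed)),
                             n_modes = cfg$n_modes)
    write_nmd(modes_bulk, file.path(cfg$outdir, "modes_bulk.nmd"))
    write_nmd(modes_imm, file.path(cfg$outdir, "modes_immobilized.nmd"))
    k_cmp <- min(3, sum(!modes_bulk$rigid), sum(!modes_imm$rigid))
    tab <- compare_frequencies(modes_bulk, modes_imm, k_modes = k_cmp)
    names(tab) <- c("mode", "freq_bulk", "freq_immobilized", "ratio")
    utils::write.csv(tab, file.path(cfg$outdir, "frequencies.csv"), row.names = FALSE)
    tab
  })

  # -- trajectory statistics -------------------------------------------
  traj_out <- stage("trajectory", {
    comb <- combine_structures(built$enz, built$sheet)
    traj <- make_trajectory(comb, cfg$traj_frames, noise_sigma = cfg$traj_sigma,
                            seed = cfg$seed + 1)
    # hold the sheet still: replace its frames with the reference coords
    sheet_idx <- n_atoms(built$enz) + seq_len(n_atoms(built$sheet))
    for (k in seq_len(n_frames(traj))) traj$coords[sheet_idx, , k] <- coords(comb)[sheet_idx, ]
    enz_idx <- seq_len(n_atoms(built$enz))
    stats_tab <- interface_statistics(traj, enz_idx, sheet_idx,
                                      contact_cutoff = cfg$contact_cutoff)
    utils::write.csv(stats_tab, file.path(cfg$outdir, "interface_stats.csv"),
                     row.names = FALSE)
    window <- min(cfg$tail_window_ps,
                  traj$times_ps[length(traj$times_ps)] - traj$times_ps[1])
    tails <- do.call(rbind, lapply(split(stats_tab, stats_tab$metric), function(d) {
      data.frame(metric = d$metric[1],
                 tail_mean = window_average(d$value, d$time_ps, window))
    }))
    utils::write.csv(tails, file.path(cfg$outdir, "tail_averages.csv"),
                     row.names = FALSE)
    list(stats = stats_tab, tails = tails)
  })

  # -- CV rates --------------------------------------------------------
  rates <- stage("cv", {
    tabs <- lapply(seq_along(cfg$ks_values), function(i) {
      make_synthetic_cv(cfg$ks_values[i], alpha = cfg$alpha, n_e = cfg$n_e,
                        T = cfg$T_K, scan_rates = cfg$scan_rates,
                        peak_noise = cfg$cv_peak_noise_mV, seed = cfg$seed + 10 + i)
    })
    names(tabs) <- names(cfg$ks_values)
    ests <- vapply(tabs, function(tb) {
      estimate_ks(tb, alpha = cfg$alpha, n_e = cfg$n_e, T = cfg$T_K)$ks
    }, numeric(1))
    ref <- names(ests)[1]
    out <- data.frame(electrode = names(ests), ks_true = unname(cfg$ks_values),
                      ks_est = unname(ests),
                      fold_vs_first = vapply(ests, fold_change, numeric(1),
                                             ks_ref = ests[[1]]))
    for (nm in names(tabs)) {
      utils::write.csv(tabs[[nm]], file.path(cfg$outdir, paste0("cv_peaks_", nm, ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(out, file.path(cfg$outdir, "rates.csv"), row.names = FALSE)
    out
  })

  invisible(list(frequencies = freq_tab, stats = traj_out$stats,
                 tail_averages = traj_out$tails, rates = rates,
                 outdir = cfg$outdir))
}
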