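#' Parameter-recovery experiments
#'
#' End-to-end experiments that generate a synthetic condition and its
#' control, run the corresponding pipeline stage, and report the recovered
#' relative change. These are the package's self-tests against its own
#' ground truth and the drivers behind the analysis scripts.
#'
#' @name recovery
NULL

#' Recover the peripheral-membrane percent change for a preset
#'
#' Renders `n_cells` cells per arm (control and preset) across multiple
#' fields, runs the full quantification (separation erosion, size filter,
#' ring extraction, pseudo-flat-field subtraction, ring means), normalizes
#' to the control mean, and reports the treated arm's mean percent.
#'
#' @param preset preset name (see [builtin_presets()])
#' @param n_cells cells per arm (default 300)
#' @param seed master seed; the two arms use seeds derived from it
#' @param noise,gradient rendering switches (default both on)
#' @param cfg a [run_config()]
#' @param n_per_field cells per rendered field
#' @param dim field edge length (px)
#' @param control_meas optional precomputed control-arm measurement table
#'   (from a previous run with the same seed), to avoid re-rendering the
#'   shared control arm
#' @return list with `mean_percent` (treated arm, control = 100),
#'   `percent_change` (`mean_percent - 100`), `summary` (group summaries),
#'   and `control_meas` (reusable control measurements)
#' @export
pm_recovery <- function(preset, n_cells = 300, seed = 1, noise = TRUE,
                        gradient = TRUE, cfg = run_config(),
                        n_per_field = 30, dim = 1200, control_meas = NULL) {
  if (is.null(control_meas)) {
    ctrl_fields <- render_cohort("control", n_cells, seed = derive_seed(seed, 100),
                                 n_per_field = n_per_field, noise = noise,
                                 gradient = gradient, dim = dim)
    control_meas <- quantify_cohort(ctrl_fields, cfg)
  }
  trt_fields <- render_cohort(preset, n_cells, seed = derive_seed(seed, 200),
                              n_per_field = n_per_field, noise = noise,
                              gradient = gradient, dim = dim)
  trt_meas <- quantify_cohort(trt_fields, cfg)
  meas <- rbind(control_meas, trt_meas)
  np <- normalize_percent(meas, control_group = "control", cfg = cfg)
  mp <- unname(np$summary$mean_percent[np$summary$group == preset])
  list(mean_percent = mp, percent_change = mp - 100,
       summary = np$summary, control_meas = control_meas)
}

#' Recover dose-response parameter changes for a preset
#'
#' Simulates 9-replicate plates for the preset and the control on the
#' half-log dose ladder, fits both Hill curves on per-dose means, and
#' records the percent changes in Emax and EC50. A single plate pair gives
#' an unbiased but noisy change estimate (the Emax ratio has a few percent
#' sampling error at cv = 0.10), so the experiment is repeated `n_sim`
#' times with independent derived seeds and the mean recovered change is
#' reported; the per-simulation values are returned for dispersion checks.
#' CI-overlap significance calls are made on the first simulated pair.
#'
#' @param preset preset name
#' @param seed master seed
#' @param replicates replicates per dose (default 9)
#' @param cv well noise coefficient of variation (default 0.10)
#' @param n_sim independent plate-pair simulations averaged (default 20)
#' @return list with `emax_change_pct` (mean of 100 * (Emax_t/Emax_c - 1)),
#'   `ec50_change_pct` (mean of 100 * (1 - EC50_t/EC50_c)), per-simulation
#'   vectors `emax_change_sims` / `ec50_change_sims`, the first pair of
#'   `hill_fit` objects, and CI-overlap calls for Emax and EC50
#' @export
dr_recovery <- function(preset, seed = 1, replicates = 9, cv = 0.10,
                        n_sim = 20) {
  emax_ch <- ec50_ch <- numeric(n_sim)
  fc1 <- ft1 <- NULL
  for (s in seq_len(n_sim)) {
    tab <- rbind(
      gen_dose_response("control", replicates, cv,
                        seed = derive_seed(seed, 300 + 2 * s)),
      gen_dose_response(preset, replicates, cv,
                        seed = derive_seed(seed, 301 + 2 * s))
    )
    fits <- fit_hill_groups(tab)
    fc <- fits[["control"]]; ft <- fits[[preset]]
    if (s == 1) { fc1 <- fc; ft1 <- ft }
    emax_ch[s] <- unname(100 * (ft$estimate["emax"] / fc$estimate["emax"] - 1))
    ec50_ch[s] <- unname(100 * (1 - ft$estimate["ec50"] / fc$estimate["ec50"]))
  }
  list(
    emax_change_pct = mean(emax_ch),
    ec50_change_pct = mean(ec50_ch),
    emax_change_sims = emax_ch, ec50_change_sims = ec50_ch,
    fit_control = fc1, fit_treated = ft1,
    emax_call = ci_overlap_significant(fc1, ft1, "emax"),
    ec50_call = ci_overlap_significant(fc1, ft1, "ec50")
  )
}

#' Recover the mean mating efficiency for a preset
#'
#' @param preset preset name (a mating preset)
#' @param seed RNG seed
#' @param n_assays assays (default 5)
#' @param n_competent expected competent colonies per assay (default 500)
#' @return list with `mean_efficiency` (%) and the per-assay table
#' @export
mating_recovery <- function(preset, seed = 1, n_assays = 5, n_competent = 500) {
  counts <- gen_mating_counts(preset, n_assays, n_competent,
                              seed = derive_seed(seed, 400 + nchar(preset)))
  eff <- mating_efficiency(counts)
  list(mean_efficiency = mean(eff$efficiency_percent), efficiencies = eff)
}

#' Recover the empty-vacuole fold change between two profile presets
#'
#' @param seed master seed
#' @param n_cells profiles per preset (default 150)
#' @param noise logical (default TRUE)
#' @param test,reference preset names (default atg8 mutant vs wild type)
#' @return list with `fold_change`, per-group `fractions`, and the
#'   classified `phenotypes`
#' @export
vacuole_recovery <- function(seed = 1, n_cells = 150, noise = TRUE,
                             test = "atg8_vacuole", reference = "wt_vacuole") {
  ref <- gen_profiles(reference, n_cells, seed = derive_seed(seed, 500), noise = noise)
  tst <- gen_profiles(test, n_cells, seed = derive_seed(seed, 501), noise = noise)
  tst$profiles$cell_id <- tst$profiles$cell_id + n_cells
  prof <- rbind(ref$profiles, tst$profiles)
  phen <- classify_profiles(prof)
  ef <- empty_fraction(phen, test = test, reference = reference)
  c(ef, list(phenotypes = phen))
}
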