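test_that("built-in presets carry the studied effect sizes", {
  ps <- builtin_presets()
  get <- function(name, col) ps[[col]][ps$name == name]
  expect_equal(get("control", "membrane_scale"), 1.0)
  expect_equal(get("rapamycin_ste2", "membrane_scale"), 0.40)
  expect_equal(get("stationary", "membrane_scale"), 0.38)
  expect_equal(get("low_nitrogen", "membrane_scale"), 0.34)
  expect_equal(get("rapamycin_pma1", "membrane_scale"), 1.16)
  expect_equal(get("ypk1_delta", "emax_scale"), 5.33)
  expect_equal(get("ypk1_delta", "ec50_scale"), 0.61)
  expect_equal(get("atg8_vacuole", "empty_vacuole_prob") /
               get("wt_vacuole", "empty_vacuole_prob"), 4.0)
  expect_equal(get("mating_control", "mating_prob"), 0.78)
  expect_error(gen_profiles("control", 5, seed = 1), "empty_vacuole_prob")
  expect_error(get_preset("nope"), "unknown preset")
})

test_that("all generators are deterministic under a fixed seed", {
  f1 <- render_field("control", 5, seed = 61, dim = 500)
  f2 <- render_field("control", 5, seed = 61, dim = 500)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$mask, f2$mask)
  expect_identical(f1$truth, f2$truth)

  expect_identical(gen_profiles("wt_vacuole", 10, seed = 62),
                   gen_profiles("wt_vacuole", 10, seed = 62))
  expect_identical(gen_dose_response("control", seed = 63),
                   gen_dose_response("control", seed = 63))
  expect_identical(gen_mating_counts("mating_control", seed = 64),
                   gen_mating_counts("mating_control", seed = 64))
})

test_that("rendered fields satisfy the pipeline's structural assumptions", {
  f <- render_field("control", 8, seed = 65, dim = 900)
  expect_true(all(f$image >= 0 & f$image <= 65535))
  expect_equal(max(f$mask), 8)
  # generated label masks survive cleaning with zero cells dropped
  cleaned <- clean_labels(f$mask, run_config())
  expect_equal(attr(cleaned, "n_kept"), 8)
  expect_equal(attr(cleaned, "n_dropped"), 0)
  # placement failure surfaces as an explicit error
  expect_error(render_field("control", 60, seed = 66, dim = 500),
               "could not place")
})

test_that("profile generator writes the phenotype structure it reports", {
  g <- gen_profiles("wt_vacuole", 20, seed = 67, noise = FALSE)
  for (id in c(1, 11)) {
    d <- g$profiles[g$profiles$cell_id == id, ]
    tr <- g$truth[g$truth$cell_id == id, ]
    # marker maxima sit at the recorded peak positions (0-based)
    pk <- find_vacuole_peaks(d$marker)
    expect_equal(d$position[pk], c(tr$peak_left, tr$peak_right))
  }
  # phenotype mix responds to the preset probability
  ga <- gen_profiles("atg8_vacuole", 200, seed = 68)
  expect_gt(mean(ga$truth$phenotype == "empty"), 0.45)
})

test_that("degenerate mating probabilities give degenerate efficiencies", {
  p1 <- builtin_presets()[1, ]; p1$mating_prob <- 1
  eff1 <- mating_efficiency(gen_mating_counts(p1, seed = 69))
  expect_true(all(eff1$efficiency_percent == 100))
  p0 <- p1; p0$mating_prob <- 0
  eff0 <- mating_efficiency(gen_mating_counts(p0, seed = 70))
  expect_true(all(eff0$efficiency_percent == 0))
})

test_that("dose-response tables hide the truth behind density scaling", {
  tab <- gen_dose_response("control", cv = 0, seed = 71)
  expect_true(all(tab$a600 > 0.6 & tab$a600 < 0.8))
  # raw fluorescence alone does not lie on the Hill curve; normalized does
  nd <- normalize_density(tab)
  truth <- hill_model(nd$means$dose_uM, 50, 1000, 1, 1.2)
  expect_equal(nd$means$mean_response, truth, tolerance = 1e-9)
  expect_gt(max(abs(tab$fluorescence - hill_model(tab$dose_uM, 50, 1000, 1, 1.2))), 50)
})
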