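make_fit <- function(lo, hi) {
  ci <- rbind(lo = c(b = 0, emax = lo, ec50 = 0, hill_n = 0),
              hi = c(b = 1, emax = hi, ec50 = 1, hill_n = 1))
  structure(list(estimate = c(b = 0.5, emax = (lo + hi) / 2, ec50 = 0.5,
                              hill_n = 0.5),
                 ci95 = ci, residual_sd = 0, n_points = 12,
                 converged = TRUE, flag = NA_character_),
            class = "hill_fit")
}

test_that("density normalization divides out A600 and averages replicates", {
  tab <- tibble::tibble(group = "g", replicate = c("r1", "r2"),
                        dose_uM = c(1, 1), fluorescence = c(900, 1100),
                        a600 = c(1, 1))
  nd <- normalize_density(tab)
  expect_equal(nd$means$mean_response, 1000)
  expect_equal(nd$means$n_replicates, 2L)

  tab2 <- tibble::tibble(group = "g", replicate = "r1", dose_uM = 0,
                         fluorescence = 600, a600 = 0.6)
  expect_equal(normalize_density(tab2)$table$normalized, 1000)

  tab2$a600 <- 0
  expect_error(normalize_density(tab2), "non-positive")
})

test_that("the Hill model hits its defining landmarks and is monotone", {
  expect_equal(hill_model(0, 50, 1000, 1, 1.2), 50)
  expect_equal(hill_model(1, 50, 1000, 1, 1.2), 50 + 500)  # dose = EC50
  expect_equal(hill_model(1e9, 50, 1000, 1, 1.2), 1050, tolerance = 1e-4)
  withr::with_seed(12, {
    for (i in 1:25) {
      b <- runif(1, 0, 100); emax <- runif(1, 0, 2000)
      ec50 <- runif(1, 0.01, 100); n <- runif(1, 0.3, 4)
      d <- sort(c(0, 10^runif(15, -3, 3)))
      y <- hill_model(d, b, emax, ec50, n)
      expect_true(all(diff(y) >= -1e-9))
    }
  })
})

test_that("noise-free generator data is refit to within 0.1%", {
  for (preset in c("control", "ypk1_delta", "atg8_delta_transcription")) {
    tab <- gen_dose_response(preset, cv = 0, seed = 41)
    fit <- fit_hill(normalize_density(tab)$means)
    ps <- builtin_presets()
    truth <- c(b = 50, emax = 1000 * ps$emax_scale[ps$name == preset],
               ec50 = 1 * ps$ec50_scale[ps$name == preset], hill_n = 1.2)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$estimate / truth - 1)), 0.001)
  }
  # a 0.74x Emax arm recovers exactly that ratio at zero noise
  f_ctrl <- fit_hill(normalize_density(gen_dose_response("control", cv = 0, seed = 42))$means)
  f_rapa <- fit_hill(normalize_density(
    gen_dose_response("rapamycin_transcription", cv = 0, seed = 43))$means)
  expect_equal(unname(f_rapa$estimate["emax"] / f_ctrl$estimate["emax"]),
               0.74, tolerance = 1e-3)
})

test_that("a flat response is flagged as no response", {
  doses <- c(0, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100, 300)
  means <- tibble::tibble(dose_uM = doses, mean_response = rep(50, 12))
  fit <- fit_hill(means)
  expect_true(!is.na(fit$flag))
  expect_lte(fit$ci95["lo", "emax"], 0)
})

test_that("CI-overlap significance calls follow the disjointness rule", {
  expect_equal(ci_overlap_significant(make_fit(1, 2), make_fit(3, 4), "emax"),
               "significant")
  expect_equal(ci_overlap_significant(make_fit(1, 3), make_fit(2, 4), "emax"),
               "not_significant")
  f <- make_fit(1, 2)
  expect_equal(ci_overlap_significant(f, f, "emax"), "not_significant")
  flagged <- make_fit(1, 2); flagged$flag <- "no response"
  expect_equal(ci_overlap_significant(f, flagged, "emax"), "indeterminate")
})

test_that("confidence intervals narrow as replication grows", {
  width <- function(n_rep) {
    ws <- sapply(1:5, function(s) {
      tab <- gen_dose_response("control", replicates = n_rep, cv = 0.10,
                               seed = 50 + 10 * s + n_rep)
      fit <- fit_hill(normalize_density(tab)$means)
      diff(fit$ci95[, "emax"])
    })
    mean(ws)
  }
  w <- c(width(3), width(9), width(27))
  expect_true(all(diff(w) < 0))
})
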