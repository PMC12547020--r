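test_that("percent normalization is per-stratum and scale-invariant", {
  meas <- tibble::tibble(
    group = c("ctrl", "ctrl", "trt"),
    mean_ring_intensity = c(200, 200, 100)
  )
  np <- normalize_percent(meas, "ctrl")
  expect_equal(np$cells$percent, c(100, 100, 50))
  expect_equal(np$summary$mean_percent[np$summary$group == "ctrl"], 100)

  # two strata, each normalized to its own control mean
  meas2 <- tibble::tibble(
    group = rep(c("ctrl", "trt"), 2),
    tp = c("t0", "t0", "t1", "t1"),
    mean_ring_intensity = c(100, 50, 400, 100)
  )
  np2 <- normalize_percent(meas2, "ctrl", stratum = "tp")
  expect_equal(np2$cells$percent, c(100, 50, 100, 25))

  # multiplying every raw value by a constant changes nothing
  meas3 <- meas; meas3$mean_ring_intensity <- meas3$mean_ring_intensity * 17
  expect_equal(normalize_percent(meas3, "ctrl")$cells$percent, np$cells$percent)

  expect_error(normalize_percent(meas, "absent"), "not present")
  neg <- meas; neg$mean_ring_intensity[1:2] <- -1
  expect_error(normalize_percent(neg, "ctrl"), "not positive")
})

test_that("Welch test matches the direct formula and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  w <- welch_t(a, b)
  o <- brute_welch(a, b)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_equal(w$t, -1.2247, tolerance = 1e-4)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.2878, tolerance = 1e-3)

  # identical samples: t = 0, two-tailed p = 1
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # one-tailed p is half the two-tailed p in the observed direction
  one <- welch_t(a, b, tails = 1, direction = "less")
  expect_equal(one$p, w$p / 2, tolerance = 1e-12)

  # antisymmetry
  w2 <- welch_t(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  expect_error(welch_t(1, b), "n >= 2")
})

test_that("bootstrap intervals are deterministic and degenerate correctly", {
  expect_equal(bootstrap_ci(rep(5, 4), B = 200, seed = 1), c(5, 5))
  ci1 <- bootstrap_ci(rnorm(30), B = 500, seed = 99)
  ci2 <- bootstrap_ci(withr::with_seed(1, rnorm(30)), B = 500, seed = 99)
  ci2b <- bootstrap_ci(withr::with_seed(1, rnorm(30)), B = 500, seed = 99)
  expect_identical(ci2, ci2b)
  expect_lt(ci1[1], ci1[2])
})

test_that("ANOVA + Tukey separates real gaps and matches the k=2 identity", {
  withr::with_seed(77, {
    vals <- c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 10), rnorm(50, 10))
    grp <- rep(c("a", "b", "c", "d"), each = 50)
  })
  at <- anova_tukey(vals, grp)
  expect_lt(at$p_overall, 1e-10)
  cross <- at$pairwise$p_adj[at$pairwise$group1 %in% c("c", "d") &
                             at$pairwise$group2 %in% c("a", "b")]
  within <- at$pairwise$p_adj[(at$pairwise$group1 == "b" & at$pairwise$group2 == "a") |
                              (at$pairwise$group1 == "d" & at$pairwise$group2 == "c")]
  expect_true(all(cross < 1e-6))
  expect_true(all(within > 0.5))
  expect_true(all(at$pairwise$p_adj >= 0 & at$pairwise$p_adj <= 1))

  # with two groups, Tukey reduces to the pooled-variance t test (q = t*sqrt(2))
  withr::with_seed(78, { x <- rnorm(12, 0); y <- rnorm(12, 0.8) })
  at2 <- anova_tukey(c(x, y), rep(c("x", "y"), each = 12))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(at2$pairwise$p_adj, tt$p.value, tolerance = 1e-9)

  expect_error(anova_tukey(c(1, 2, 3), c("a", "a", "b")), "n >= 2")
})

test_that("rescue categories are a pure function of the two significance bits", {
  expect_equal(classify_rescue(0.001, 0.80)$category, "no_rescue")
  expect_equal(classify_rescue(0.001, 0.001)$category, "partial_rescue")
  expect_equal(classify_rescue(0.60, 0.01)$category, "complete_rescue")
  expect_equal(classify_rescue(0.60, 0.80)$category, "indeterminate")
  # exhaustive over the bit combinations at the alpha boundary
  for (pu in c(0.049, 0.051)) for (pt in c(0.049, 0.051)) {
    got <- classify_rescue(pu, pt, alpha = 0.05)$category
    want <- if (pu < 0.05 && pt >= 0.05) "no_rescue"
      else if (pu < 0.05 && pt < 0.05) "partial_rescue"
      else if (pu >= 0.05 && pt < 0.05) "complete_rescue"
      else "indeterminate"
    expect_equal(got, want)
  }
})

test_that("rescue classification works end to end on simulated groups", {
  withr::with_seed(101, {
    meas <- tibble::tibble(
      group = rep(c("wt_untreated", "wt_treated", "mut_untreated", "mut_treated"),
                  each = 60),
      mean_ring_intensity = c(rnorm(60, 4000, 300), rnorm(60, 1600, 300),
                              rnorm(60, 4000, 300), rnorm(60, 4000, 300))
    )
  })
  res <- rescue_classify(meas, "wt_untreated", "wt_treated",
                         "mut_untreated", "mut_treated")
  expect_equal(res$category, "complete_rescue")
  expect_error(rescue_classify(meas[meas$group != "wt_treated", ],
                               "wt_untreated", "wt_treated",
                               "mut_untreated", "mut_treated"),
               "missing group")
})

test_that("mating efficiency is the dilution-corrected diploid percentage", {
  counts <- tibble::tibble(
    assay_id = c("a1", "a2"), treatment = "ctrl",
    competent_colonies = c(100, 50), diploid_colonies = c(50, 39),
    dilution_competent = c(1, 100), dilution_diploid = c(1, 10)
  )
  eff <- mating_efficiency(counts)
  expect_equal(eff$efficiency_percent, c(50, 7.8))

  bad <- counts; bad$diploid_colonies[1] <- 200
  expect_error(mating_efficiency(bad), "exceeds competent")
  zero <- counts; zero$competent_colonies[2] <- 0
  expect_error(mating_efficiency(zero), "zero mating-competent")

  withr::with_seed(9, {
    e2 <- rbind(
      mating_efficiency(gen_mating_counts("mating_control", seed = 1)),
      mating_efficiency(gen_mating_counts("mating_rapamycin", seed = 2))
    )
  })
  cmp <- compare_mating(e2, treated = "mating_rapamycin", control = "mating_control")
  expect_lt(cmp$test$p, 0.05)
  expect_lt(cmp$mean_treated, cmp$mean_control)
})
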