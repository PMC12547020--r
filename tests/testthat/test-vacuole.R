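test_that("line sampling degenerates correctly and interpolates bilinearly", {
  withr::with_seed(5, img <- matrix(runif(100, 0, 10), 10, 10))
  # horizontal segment: exact pixel values of that row span
  expect_equal(sample_line(img, c(4, 2), c(4, 8)), img[4, 2:8])
  # zero-length segment: single sample
  expect_equal(sample_line(img, c(3, 3), c(3, 3)), img[3, 3])
  # diagonal across a constant image: constant series
  cimg <- matrix(4.2, 12, 12)
  expect_equal(sample_line(cimg, c(1, 1), c(12, 12)), rep(4.2, 17))
  expect_error(sample_line(img, c(0, 1), c(5, 5)), "outside")
})

test_that("peak finding picks the two most prominent admissible maxima", {
  # hand example: two clear peaks at 1-based indices 3 and 7
  expect_equal(find_vacuole_peaks(c(1, 2, 10, 3, 2, 3, 10, 2, 1), min_sep = 3),
               c(3, 7))
  # monotone series has no interior maximum
  expect_true(anyNA(find_vacuole_peaks(1:20, min_sep = 3)))
  # three maxima with prominences 5, 9, 8: the 9 and 8 peaks win
  x <- rep(0, 50)
  x[10] <- 5; x[25] <- 9; x[40] <- 8
  expect_equal(find_vacuole_peaks(x, min_sep = 10), c(25, 40))
  # oracle: enumerate admissible pairs, rank by sorted prominence
  pairs <- t(combn(c(10, 25, 40), 2))
  proms <- c(`10` = 5, `25` = 9, `40` = 8)
  scores <- apply(pairs, 1, function(p) sort(proms[as.character(p)], decreasing = TRUE))
  best <- pairs[order(scores[1, ], scores[2, ], decreasing = TRUE)[1], ]
  expect_equal(find_vacuole_peaks(x, min_sep = 10), unname(best))
})

test_that("vacuole classification reproduces the hand-computed example", {
  marker <- c(1, 2, 10, 3, 2, 3, 10, 2, 1)
  cargo <- c(0, 0, 5, 1, 1, 1, 5, 0, 0)
  res <- classify_vacuole(marker, cargo, min_sep = 3)
  expect_equal(res$mem_mean, 2)     # mean(0,5,1,1,5,0)
  expect_equal(res$lum_mean, 1)     # cargo[5]
  expect_equal(res$ratio, 0.5)
  expect_equal(res$klass, "empty")

  # constant cargo: ratio exactly 1 classifies full (tie rule)
  res1 <- classify_vacuole(marker, rep(3, 9), min_sep = 3)
  expect_equal(res1$ratio, 1)
  expect_equal(res1$klass, "full")

  # lumen plateau at 3x the membrane shoulder level: ratio 3, full
  cargo3 <- c(0, 2, 2, 2, 6, 2, 2, 2, 0)
  res3 <- classify_vacuole(marker, cargo3, min_sep = 3)
  expect_equal(res3$ratio, 3)
  expect_equal(res3$klass, "full")

  # non-positive membrane mean is unclassifiable
  resb <- classify_vacuole(marker, rep(0, 9), min_sep = 3)
  expect_equal(resb$klass, "unclassifiable")
})

test_that("classification is reversal-invariant and cargo-scale-invariant", {
  gp <- gen_profiles("wt_vacuole", 25, seed = 31)
  for (id in unique(gp$profiles$cell_id)[1:10]) {
    d <- gp$profiles[gp$profiles$cell_id == id, ]
    fwd <- classify_vacuole(d$marker, d$cargo)
    rev_ <- classify_vacuole(rev(d$marker), rev(d$cargo))
    expect_equal(rev_$ratio, fwd$ratio, tolerance = 1e-12)
    expect_equal(rev_$klass, fwd$klass)
    sc <- classify_vacuole(d$marker, d$cargo * 7.3)
    expect_equal(sc$ratio, fwd$ratio, tolerance = 1e-12)
    expect_equal(sc$klass, fwd$klass)
  }
})

test_that("classifier recovers generator truth", {
  # noise off: perfect agreement
  g0 <- gen_profiles("atg8_vacuole", 60, seed = 32, noise = FALSE)
  ph0 <- classify_profiles(g0$profiles)
  expect_equal(ph0$klass[order(ph0$cell_id)],
               g0$truth$phenotype[order(g0$truth$cell_id)])
  # preset noise: at least 95% agreement
  g1 <- gen_profiles("atg8_vacuole", 60, seed = 33, noise = TRUE)
  ph1 <- classify_profiles(g1$profiles)
  agree <- mean(ph1$klass[order(ph1$cell_id)] ==
                g1$truth$phenotype[order(g1$truth$cell_id)])
  expect_gte(agree, 0.95)
})

test_that("empty fractions and fold changes follow their definitions", {
  ph <- tibble::tibble(cell_id = 1:8,
                       group = rep(c("a", "b"), each = 4),
                       klass = c("empty", "empty", "full", "full",
                                 "full", "full", "full", "full"))
  ef <- empty_fraction(ph, test = "a", reference = "b")
  expect_equal(ef$fractions$empty_fraction[ef$fractions$group == "a"], 0.5)
  # reference fraction 0 -> fold undefined
  expect_true(is.na(ef$fold_change))

  ph$klass[5] <- "empty"
  ef2 <- empty_fraction(ph, test = "a", reference = "b")
  expect_equal(ef2$fold_change, 0.5 / 0.25)
  expect_error(empty_fraction(ph, test = "zz", reference = "b"), "unknown group")
})
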