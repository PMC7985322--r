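test_that("partition statistics match hand arithmetic on the worked scene", {
  ts <- toy_scene()
  m <- partition_stats(ts$frame, ts$seg, background = 0)
  expect_identical(m$area_dense, 4L)
  expect_equal(m$mean_dense, 100)
  expect_equal(m$mean_dilute, 10)
  expect_equal(m$total_integrated_density, 1360)
  expect_equal(m$fraction_in_condensate, 360 / 1360, tolerance = 1e-12)

  # redistributed uniformly: no mask, fraction 0, flagged not failed
  flat <- matrix(13.6, 10, 10)
  seg0 <- list(condensate_mask = matrix(FALSE, 10, 10),
               cell_mask = matrix(TRUE, 10, 10))
  m0 <- partition_stats(flat, seg0, 0)
  expect_identical(m0$fraction_in_condensate, 0)
  expect_true(m0$empty_condensate)
})

test_that("partition statistics are shift- and scale-invariant with matched background", {
  ts <- toy_scene()
  base <- partition_stats(ts$frame, ts$seg, 0)
  shifted <- partition_stats(ts$frame + 5, ts$seg, 5)
  expect_equal(shifted$fraction_in_condensate, base$fraction_in_condensate,
               tolerance = 1e-12)
  scaled <- partition_stats(ts$frame * 3.25, ts$seg, 0)
  expect_equal(scaled$fraction_in_condensate, base$fraction_in_condensate,
               tolerance = 1e-12)
  expect_equal(condensate_intensity_ratio(ts$frame + 5, ts$seg, 5), ts$ratio,
               tolerance = 1e-12)
  expect_equal(condensate_intensity_ratio(ts$frame * 3.25, ts$seg, 0), ts$ratio,
               tolerance = 1e-12)
})

test_that("disruption efficiency follows the pre/post fraction formula", {
  ts <- toy_scene()
  pre <- partition_stats(ts$frame, ts$seg, 0)
  seg0 <- list(condensate_mask = matrix(FALSE, 10, 10),
               cell_mask = matrix(TRUE, 10, 10))
  post0 <- partition_stats(matrix(13.6, 10, 10), seg0, 0)
  expect_equal(disruption_efficiency(pre, post0)$efficiency_percent, 100)

  mk <- function(f) list(fraction_in_condensate = f, mean_dense = 2,
                         mean_dilute = 1, empty_condensate = FALSE)
  expect_equal(disruption_efficiency(mk(0.4), mk(0.1))$efficiency_percent, 75)
  expect_error(disruption_efficiency(mk(0), mk(0.1)), "undefined")

  grown <- disruption_efficiency(mk(0.2), mk(0.3))
  expect_lt(grown$efficiency_percent, 0)
  expect_true(grown$grew)
})

test_that("efficiency is monotone decreasing in fraction_post for fixed fraction_pre", {
  mk <- function(f) list(fraction_in_condensate = f, mean_dense = 2,
                         mean_dilute = 1, empty_condensate = FALSE)
  effs <- vapply(seq(0, 0.4, by = 0.05),
                 function(fp) disruption_efficiency(mk(0.4), mk(fp))$efficiency_percent,
                 numeric(1))
  expect_true(all(diff(effs) < 0))
  expect_true(all(effs <= 100))
})

test_that("condensate intensity ratio matches hand arithmetic and its limits", {
  ts <- toy_scene()
  expect_equal(condensate_intensity_ratio(ts$frame, ts$seg, 0), 400 / 1360,
               tolerance = 1e-12)
  seg0 <- list(condensate_mask = matrix(FALSE, 10, 10),
               cell_mask = matrix(TRUE, 10, 10))
  expect_identical(condensate_intensity_ratio(ts$frame, seg0, 0), 0)
  # all signal in condensates
  all_in <- matrix(0, 10, 10); all_in[5:6, 5:6] <- 100
  expect_equal(condensate_intensity_ratio(all_in, ts$seg, 0), 1)
})

test_that("background estimation equals the loop-computed outside mean", {
  frame <- matrix(5, 20, 20)
  cell <- matrix(FALSE, 20, 20); cell[8:12, 8:12] <- TRUE
  expect_equal(estimate_background(frame, cell), 5)
  frame2 <- matrix(0, 20, 20); frame2[8:12, 8:12] <- 50
  expect_equal(estimate_background(frame2, cell), 0)

  set.seed(21)
  noisy <- matrix(rnorm(400, 12, 2), 20, 20)
  grown <- EBImage::dilate(cell * 1, EBImage::makeBrush(7, "disc")) > 0
  acc <- 0; n <- 0
  for (i in seq_along(noisy)) if (!grown[i]) { acc <- acc + noisy[i]; n <- n + 1 }
  expect_equal(estimate_background(noisy, cell), acc / n, tolerance = 1e-12)
  expect_error(estimate_background(frame, matrix(TRUE, 20, 20)), "explicit background")
})

test_that("uptake percent follows the background-subtracted mean ratio", {
  expect_equal(uptake_percent(rep(50, 5), rep(100, 5), 0), 50)
  expect_equal(uptake_percent(rep(80, 7), rep(80, 3), 0), 100)
  expect_equal(uptake_percent(rep(60, 5), rep(110, 5), 10), 50)
  expect_error(uptake_percent(c(50), c(5), 10), "undefined")
})

test_that("efficiency-ratio correlation recovers exact and generative lines", {
  mk <- function(eff, ratio) list(efficiency_percent = eff, dense_dilute_ratio = ratio)
  exact <- lapply(1:5, function(i) mk(100 - 10 * i, i))
  fit <- efficiency_ratio_correlation(exact)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-12)
  expect_equal(fit$slope, -10, tolerance = 1e-9)

  expect_error(efficiency_ratio_correlation(lapply(1:4, function(i) mk(i, 2))),
               "zero variance")

  set.seed(14)
  ratio <- runif(40, 1, 8)
  eff <- 95 - 7 * ratio + rnorm(40, 0, 4)
  cohort <- Map(mk, eff, ratio)
  g <- efficiency_ratio_correlation(cohort)
  se_slope <- summary(lm(eff ~ ratio))$coefficients[2, 2]
  expect_lt(abs(g$slope - (-7)), 3 * se_slope)
  expect_lt(g$pearson_r, -0.8)
})
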