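sample_sigmoid <- function(t, base = 0.1, amplitude = 0.9, t_half = 60, tau = 30) {
  base + amplitude / (1 + exp((t - t_half) / tau))
}

test_that("noiseless sigmoid samples return the generating tau", {
  t <- seq(0, 180, by = 2)
  fit <- fit_sigmoid(timecourse(t, sample_sigmoid(t)))
  expect_true(fit$converged)
  expect_equal(fit$tau_s, 30, tolerance = 1e-3 / 30)
  expect_equal(fit$t_half_s, 60, tolerance = 1e-4)
  expect_equal(fit$base, 0.1, tolerance = 1e-6)
  expect_gt(fit$r_squared, 0.999999)
})

test_that("noiseless exponential samples return the generating tau in both regimes", {
  t <- seq(0, 400, by = 4)
  v <- 0.05 + 0.95 * exp(-t / 65)
  fit <- fit_exponential(timecourse(t, v), t_start_s = 0)
  expect_equal(fit$tau_s, 65, tolerance = 1e-3 / 65)

  t2 <- seq(0, 1200, by = 10)  # 20 min sampled
  v2 <- 2 + 8 * exp(-t2 / 472)
  fit2 <- fit_exponential(timecourse(t2, v2), t_start_s = 0)
  expect_equal(fit2$tau_s, 472, tolerance = 0.1 / 472)
})

test_that("degenerate series yield converged = FALSE, never a fabricated tau", {
  t <- seq(0, 100, by = 5)
  flat <- fit_sigmoid(timecourse(t, rep(3, length(t))))
  expect_false(flat$converged)
  expect_true(is.na(flat$tau_s))
  short <- fit_sigmoid(timecourse(1:4, c(1, 0.8, 0.4, 0.1)))
  expect_false(short$converged)
  expect_false(fit_exponential(timecourse(t, rep(1, length(t))), 0)$converged)
  expect_error(compare_taus(flat, flat), "converged")
})

test_that("tau is equivariant to time shift and scale and invariant to value scale", {
  t <- seq(0, 180, by = 3)
  v <- sample_sigmoid(t)
  ref <- fit_sigmoid(timecourse(t, v))
  shifted <- fit_sigmoid(timecourse(t + 42, v))
  expect_equal(shifted$tau_s, ref$tau_s, tolerance = 1e-6)
  expect_equal(shifted$t_half_s, ref$t_half_s + 42, tolerance = 1e-4)
  scaled_t <- fit_sigmoid(timecourse(t * 2.5, v))
  expect_equal(scaled_t$tau_s, 2.5 * ref$tau_s, tolerance = 1e-6)
  scaled_v <- fit_sigmoid(timecourse(t, v * 1000))
  expect_equal(scaled_v$tau_s, ref$tau_s, tolerance = 1e-6)

  ve <- 0.2 + 0.8 * exp(-pmax(t - 20, 0) / 40)
  refe <- fit_exponential(timecourse(t, ve), 20)
  expect_equal(fit_exponential(timecourse(t * 3, ve), 60)$tau_s, 3 * refe$tau_s,
               tolerance = 1e-6)
  expect_equal(fit_exponential(timecourse(t, ve * 7), 20)$tau_s, refe$tau_s,
               tolerance = 1e-6)
})

test_that("exponential and sigmoid fits agree far past the midpoint", {
  # for t >> t_half the logistic is base + amplitude*exp(-(t - t_half)/tau)
  t <- seq(180, 600, by = 6)  # starts 4 time constants past the midpoint
  v <- sample_sigmoid(t, base = 0.1, amplitude = 0.9, t_half = 20, tau = 40)
  fs <- fit_sigmoid(timecourse(t, v))
  fe <- fit_exponential(timecourse(t, v), t_start_s = 180)
  expect_true(fs$converged && fe$converged)
  expect_lt(abs(fs$tau_s - fe$tau_s) / fe$tau_s, 0.05)
})

test_that("noisy sigmoid recovery stays within 15% of truth in >= 95% of seeds", {
  # 60 frames with >= 4 tau of plateau on both sides of the midpoint
  t <- seq(0, by = 5, length.out = 60)
  truth <- sample_sigmoid(t, base = 0, amplitude = 1, t_half = 120, tau = 30)
  taus <- vapply(1:100, function(s) {
    set.seed(s)
    fit <- fit_sigmoid(timecourse(t, truth + rnorm(length(t), 0, 0.05)))
    if (fit$converged) fit$tau_s else NA_real_
  }, numeric(1))
  ok <- abs(taus - 30) / 30 <= 0.15
  expect_gte(mean(ok, na.rm = FALSE), 0.95)
})

test_that("condensate timecourse matches the simulator closed form on noiseless movies", {
  cfg <- quick_config(seed = 4, n_frames = 40, frame_interval_s = 5,
                      kinetics_model = "sigmoid_decay", tau_s = 30, onset_s = 60,
                      noise_gain = 0, read_noise_sd = 0)
  sim <- simulate_dissolution_movie(cfg)
  seg <- list(condensate_mask = sim$truth$true_condensate_mask,
              cell_mask = sim$truth$true_cell_mask)
  class(seg) <- "segmentation"
  tc <- condensate_timecourse(sim$stack, seg, cfg$background_level, onset_s = 60)
  scaled <- tc$values / tc$values[1] * sim$truth$excess_factor[1]
  expect_equal(scaled, sim$truth$excess_factor, tolerance = 1e-6)

  cc <- simulate_dissolution_movie(quick_config(seed = 4, n_frames = 6,
                                                kinetics_model = "constant",
                                                noise_gain = 0, read_noise_sd = 0))
  tcc <- condensate_timecourse(cc$stack, seg, cfg$background_level)
  expect_lt(diff(range(tcc$values)) / mean(tcc$values), 1e-9)

  # all-empty masks: zero series, flagged
  empty <- seg; empty$condensate_mask <- matrix(FALSE, 64, 64)
  expect_warning(tc0 <- condensate_timecourse(cc$stack, empty, 0), "empty")
  expect_true(all(tc0$values == 0))
  expect_identical(tc0$n_empty, cc$stack$n_frames)
})

test_that("tau fold change propagates uncertainty and hits the arithmetic", {
  mk <- function(tau, se) structure(list(tau_s = tau, converged = TRUE,
                                         param_uncertainties = c(tau = se)),
                                    class = "kinetic_fit")
  cmp <- compare_taus(mk(472, 59), mk(65, 8))
  expect_equal(cmp$fold, 472 / 65, tolerance = 1e-12)  # ~7.26
  expect_equal(cmp$se, (472 / 65) * sqrt((59 / 472)^2 + (8 / 65)^2),
               tolerance = 1e-12)
  expect_equal(compare_taus(mk(30, 1), mk(30, 1))$fold, 1)
})

test_that("paired movies with taus in an 8:1 ratio recover the fold change", {
  fit_movie <- function(tau, n_frames, dt, seed) {
    cfg <- quick_config(seed = seed, n_frames = n_frames, frame_interval_s = dt,
                        kinetics_model = "exponential_decay", tau_s = tau,
                        onset_s = 20)
    sim <- simulate_dissolution_movie(cfg, keep_expected = FALSE)
    seg <- make_masks(get_frame(sim$stack, 1))
    bg <- estimate_background(get_frame(sim$stack, 1), seg$cell_mask)
    fit_exponential(condensate_timecourse(sim$stack, seg, bg, onset_s = 20), 20)
  }
  fa <- fit_movie(320, 60, 25, 31)
  fb <- fit_movie(40, 60, 4, 32)
  cmp <- compare_taus(fa, fb)
  expect_lt(abs(cmp$fold - 8) / 8, 0.2)
})
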