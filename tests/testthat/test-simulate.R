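noiseless <- function(...) quick_config(..., noise_gain = 0, read_noise_sd = 0)

test_that("noise-free dissolution movies conserve total expected intensity", {
  for (model in c("sigmoid_decay", "exponential_decay")) {
    sim <- simulate_dissolution_movie(noiseless(seed = 2, kinetics_model = model))
    totals <- apply(sim$stack$pixels, 3, sum)
    expect_lt(diff(range(totals)) / mean(totals), 1e-9)
  }
})

test_that("constant kinetics without noise reproduces frame 0 exactly", {
  sim <- simulate_dissolution_movie(noiseless(seed = 3, kinetics_model = "constant"))
  for (i in 2:sim$stack$n_frames) {
    expect_identical(sim$stack$pixels[, , i], sim$stack$pixels[, , 1])
  }
})

test_that("true condensate fraction follows the closed-form logistic", {
  # scalar oracle, written independently of the renderer: the dense excess
  # carries factor 1/(1+exp((t - t_mid)/tau)) and the measured fraction is
  # proportional to it, so fraction(t) = fraction(t0) * f(t)/f(t0)
  cfg <- noiseless(seed = 4, n_frames = 40, frame_interval_s = 5,
                   kinetics_model = "sigmoid_decay", tau_s = 30, onset_s = 60)
  sim <- simulate_dissolution_movie(cfg)
  t <- sim$truth$times_s
  logistic <- 1 / (1 + exp((t - (60 + 3 * 30)) / 30))
  predicted <- sim$truth$true_fraction[1] * logistic / logistic[1]
  expect_equal(sim$truth$true_fraction, predicted, tolerance = 1e-9)
  # spot check at t = t_mid + tau*log(3): logistic value exactly 1/4
  t_q <- (60 + 90) + 30 * log(3)
  f_q <- approx(t, sim$truth$true_fraction, xout = t_q)$y
  expect_equal(f_q / (sim$truth$true_fraction[1] / logistic[1]), 0.25,
               tolerance = 0.01)  # linear interpolation between frames
})

test_that("true fraction is monotone for decay and growth models and stays in [0,1]", {
  dec <- simulate_dissolution_movie(noiseless(seed = 6, kinetics_model = "sigmoid_decay"))
  expect_true(all(diff(dec$truth$true_fraction) <= 1e-12))
  gro <- simulate_dissolution_movie(noiseless(seed = 6, kinetics_model = "sigmoid_growth"))
  expect_true(all(diff(gro$truth$true_fraction) >= -1e-12))
  for (tr in list(dec$truth, gro$truth)) {
    expect_true(all(tr$true_fraction >= 0 & tr$true_fraction <= 1))
  }
})

test_that("identical config and seed give bit-identical stacks", {
  a <- simulate_dissolution_movie(quick_config(seed = 9))
  b <- simulate_dissolution_movie(quick_config(seed = 9))
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(serialize(a$stack$pixels, NULL), serialize(b$stack$pixels, NULL))
  c <- simulate_dissolution_movie(quick_config(seed = 10))
  expect_false(identical(a$stack$pixels, c$stack$pixels))
})

test_that("background noise statistics match the Poisson + read-noise model", {
  cfg <- sim_config(image_shape = c(160L, 160L), n_frames = 1L,
                    frame_interval_s = 1, n_droplets = 2L,
                    background_level = 30, dilute_level = 50,
                    noise_gain = 1, read_noise_sd = 2, seed = 12)
  sim <- simulate_dissolution_movie(cfg, keep_expected = FALSE)
  outside <- !sim$truth$true_cell_mask
  px <- sim$stack$pixels[, , 1][outside]
  expect_gt(length(px), 1e4)
  sigma2 <- 1 * 30 + 2^2
  expect_lt(abs(mean(px) - 30), 3 * sqrt(sigma2 / length(px)))
  chi <- (length(px) - 1) * var(px) / sigma2
  expect_gt(chi, qchisq(1e-4, length(px) - 1))
  expect_lt(chi, qchisq(1 - 1e-4, length(px) - 1))
})

test_that("droplet placement fails loudly when droplets cannot fit", {
  cfg <- quick_config(seed = 1, n_droplets = 60L, droplet_radius_px = c(8, 9))
  expect_error(simulate_dissolution_movie(cfg), "placement failed")
  expect_error(sim_config(tau_s = -5), "tau_s")
})

test_that("nuclear droplet quota lands droplets inside the nucleus", {
  cfg <- sim_config(image_shape = c(96L, 96L), n_frames = 2L, n_droplets = 4L,
                    droplet_radius_px = c(3, 4),
                    nucleus_center = c(48, 48), nucleus_semi_axes = c(16, 16),
                    nuclear_droplet_fraction = 0.5, seed = 8,
                    noise_gain = 0, read_noise_sd = 0)
  sim <- simulate_dissolution_movie(cfg)
  dr <- sim$truth$droplets
  in_nuc <- ((dr$y - 48) / 16)^2 + ((dr$x - 48) / 16)^2 <= 1
  expect_identical(sum(in_nuc), 2L)
})

test_that("blocking endpoint pair reports correct true intensity ratios", {
  base <- list(image_shape = c(64L, 64L), n_frames = 1L, frame_interval_s = 1,
               noise_gain = 0, read_noise_sd = 0, seed = 2,
               kinetics_model = "constant")
  # blocked: all signal dilute; unblocked shifts the same total into droplets
  blocked <- do.call(sim_config, c(base, list(n_droplets = 0L, dilute_level = 60)))
  unblocked <- do.call(sim_config, c(base, list(n_droplets = 3L,
                                                droplet_radius_px = c(3, 4),
                                                dilute_level = 50,
                                                partition_coefficient = 5)))
  pair <- suppressWarnings(simulate_blocking_endpoint(unblocked, blocked))
  expect_identical(pair$truth$true_ratio_blocked, 0)
  expect_gt(pair$truth$true_ratio_droplets, 0)

  # dilute_level = 0: every photon in the dense phase, ratio approaches 1
  allin <- do.call(sim_config, c(base, list(
    n_droplets = 2L, droplet_radius_px = c(4, 5), dilute_level = 0,
    dense_excess_level = 200, background_level = 0)))
  pair2 <- suppressWarnings(simulate_blocking_endpoint(allin, blocked))
  v <- pair2$truth$expected_droplets
  total <- sum(v[pair2$truth$true_cell_mask])
  inmask <- sum(v[pair2$truth$true_condensate_mask_droplets])
  # anti-aliased rims hold the remainder; the binary-mask ratio nears 1
  expect_gt(inmask / total, 0.9)
  expect_error(simulate_blocking_endpoint(
    unblocked, do.call(sim_config, c(base[names(base) != "image_shape"],
                                     list(image_shape = c(32L, 32L), n_droplets = 0L)))),
    "geometry")
})

test_that("FRAP simulation honors immobile and fully mobile limits", {
  cfg <- noiseless(seed = 5, n_frames = 30, frame_interval_s = 5,
                   n_droplets = 2L, droplet_radius_px = c(5, 6),
                   kinetics_model = "constant")
  imm <- simulate_frap_movie(cfg, bleach_frame = 5, bleach_depth = 0.7,
                             mobile_fraction = 0, exchange_tau_s = 20)
  expect_true(all(abs(imm$truth$expected_normalized[5:30]) < 1e-12))

  mob <- simulate_frap_movie(cfg, bleach_frame = 5, bleach_depth = 0.7,
                             mobile_fraction = 1, exchange_tau_s = 1e-6)
  expect_true(all(abs(mob$truth$expected_normalized[6:30] - 1) < 1e-9))

  expect_error(simulate_frap_movie(cfg, bleach_frame = 5,
                                   bleach_region = matrix(TRUE, 64, 64)),
               "outside the cell")
  expect_error(simulate_frap_movie(cfg, bleach_frame = 1), "pre-bleach")
})

test_that("FRAP normalized plateau equals the mobile fraction on noise-free movies", {
  cfg <- noiseless(seed = 7, n_frames = 60, frame_interval_s = 5,
                   n_droplets = 2L, droplet_radius_px = c(5, 6),
                   kinetics_model = "constant")
  fr <- simulate_frap_movie(cfg, bleach_frame = 6, bleach_depth = 0.7,
                            mobile_fraction = 0.2, exchange_tau_s = 14)
  tr <- measure_frap(fr$stack, fr$truth$bleach_region, fr$truth$true_cell_mask,
                     6, background = cfg$background_level)
  tr <- normalize_frap(tr)
  # t = 270 s after the bleach is 19 exchange time constants out
  expect_equal(recovery_at(tr, 270), 0.2, tolerance = 1e-6)
})
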