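#' Parameter-recovery studies on simulated movies
#'
#' Each study simulates seeded movies under a fixed imaging regime
#' (96 x 96 px cell, dilute level 50 photons/px, partition coefficient 6,
#' background 10, unit-gain shot noise with read noise sd 2 — a dense-phase
#' SNR of about 14), runs the full estimation path (segmentation,
#' background estimation, partition statistics, curve fitting) and returns
#' per-seed estimates next to the ground truth, so recovery accuracy can
#' be summarized by the caller.
#'
#' @name recovery_studies
NULL

.study_config <- function(seed, ...) {
  args <- list(image_shape = c(96L, 96L), n_droplets = 6L,
               droplet_radius_px = c(3, 5), dilute_level = 50,
               partition_coefficient = 6, background_level = 10,
               noise_gain = 1, read_noise_sd = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# fixed sampling regimes per characteristic time, sized so the movie spans
# the transition (sigmoid) or >= 3 decay constants (exponential)
.tau_regimes <- list(
  `22` = list(model = "sigmoid_decay", n_frames = 100L, dt = 2, onset = 30),
  `30` = list(model = "sigmoid_decay", n_frames = 100L, dt = 3, onset = 60),
  `65` = list(model = "exponential_decay", n_frames = 80L, dt = 5, onset = 60),
  `472` = list(model = "exponential_decay", n_frames = 100L, dt = 15, onset = 100))

#' @describeIn recovery_studies Simulate dissolution movies with known tau
#'   and re-estimate it by segmenting the pre-treatment frame, measuring
#'   the integrated-excess timecourse on that fixed footprint, and fitting
#'   the matching model (sigmoid for the 22/30 s regimes, exponential for
#'   65/472 s, mirroring which model suits which construct class).
#' @param tau_s true characteristic time; one of 22, 30, 65, 472 for the
#'   preset regimes, or any value with an explicit `regime` list
#'   (`model`, `n_frames`, `dt`, `onset`).
#' @param seeds integer vector of simulation seeds.
#' @param regime optional regime override.
#' @return `tau_recovery_study`: data.frame with `seed`, `tau_true`,
#'   `tau_est`, `converged`.
#' @export
tau_recovery_study <- function(tau_s, seeds = 1:20, regime = NULL) {
  reg <- regime %||% .tau_regimes[[as.character(tau_s)]]
  if (is.null(reg)) stop("no preset regime for tau_s = ", tau_s,
                         "; supply `regime`")
  rows <- lapply(seeds, function(s) {
    cfg <- .study_config(s, n_frames = reg$n_frames, frame_interval_s = reg$dt,
                         kinetics_model = reg$model, tau_s = tau_s,
                         onset_s = reg$onset)
    sim <- simulate_dissolution_movie(cfg, keep_expected = FALSE)
    seg <- make_masks(get_frame(sim$stack, 1))
    bg <- estimate_background(get_frame(sim$stack, 1), seg$cell_mask)
    tc <- condensate_timecourse(sim$stack, seg, bg, onset_s = reg$onset)
    fit <- if (reg$model == "sigmoid_decay") fit_sigmoid(tc) else
      fit_exponential(tc, t_start_s = reg$onset)
    data.frame(seed = s, tau_true = tau_s,
               tau_est = fit$tau_s, converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' @describeIn recovery_studies Simulate partial-dissolution movies with a
#'   known true disruption efficiency (via the residual excess fraction)
#'   and re-estimate it from pre/post partition statistics measured on the
#'   pre-treatment condensate footprint.
#' @param efficiency_percent nominal true efficiency (the residual excess
#'   is `1 - efficiency_percent/100`).
#' @return `efficiency_recovery_study`: data.frame with `seed`,
#'   `efficiency_true` (ground-truth value of the rendered movie),
#'   `efficiency_nominal`, `efficiency_est`.
#' @export
efficiency_recovery_study <- function(efficiency_percent, seeds = 1:20) {
  rows <- lapply(seeds, function(s) {
    cfg <- .study_config(s, n_frames = 100L, frame_interval_s = 3,
                         kinetics_model = "sigmoid_decay", tau_s = 30,
                         onset_s = 30,
                         residual_fraction = 1 - efficiency_percent / 100)
    sim <- simulate_dissolution_movie(cfg, keep_expected = FALSE)
    seg <- make_masks(get_frame(sim$stack, sim$truth$pre_frame))
    bg <- estimate_background(get_frame(sim$stack, 1), seg$cell_mask)
    pre <- partition_stats(get_frame(sim$stack, sim$truth$pre_frame), seg, bg)
    post <- partition_stats(get_frame(sim$stack, sim$truth$post_frame), seg, bg)
    data.frame(seed = s,
               efficiency_true = sim$truth$true_efficiency_percent,
               efficiency_nominal = efficiency_percent,
               efficiency_est = disruption_efficiency(pre, post)$efficiency_percent)
  })
  do.call(rbind, rows)
}

#' @describeIn recovery_studies Simulate FRAP movies with known mobile
#'   fraction (bleach depth 0.7, exchange tau 40 s) and read the
#'   normalized plateau at 300 s (7.5 exchange time constants) after the
#'   bleach.
#' @param mobile_fraction true mobile fraction in `[0, 1]`.
#' @return `frap_recovery_study`: data.frame with `seed`, `mobile_true`,
#'   `plateau_est`.
#' @export
frap_recovery_study <- function(mobile_fraction, seeds = 1:20) {
  rows <- lapply(seeds, function(s) {
    cfg <- .study_config(s, n_frames = 80L, frame_interval_s = 5,
                         n_droplets = 3L, droplet_radius_px = c(5, 6),
                         kinetics_model = "constant")
    fr <- simulate_frap_movie(cfg, bleach_frame = 10L, bleach_depth = 0.7,
                              mobile_fraction = mobile_fraction,
                              exchange_tau_s = 40, keep_expected = FALSE)
    bg <- estimate_background(get_frame(fr$stack, 1), fr$truth$true_cell_mask)
    tr <- normalize_frap(measure_frap(fr$stack, fr$truth$bleach_region,
                                      fr$truth$true_cell_mask, 10L, bg))
    data.frame(seed = s, mobile_true = mobile_fraction,
               plateau_est = recovery_at(tr, 300))
  })
  do.call(rbind, rows)
}

#' @describeIn recovery_studies Segment single noisy frames and score the
#'   Jaccard overlap between the recovered and true condensate masks.
#' @param partition_coefficient dense/dilute intensity ratio of the scene.
#' @return `segmentation_fidelity_study`: data.frame with `seed`,
#'   `jaccard`.
#' @export
segmentation_fidelity_study <- function(seeds = 1:20, partition_coefficient = 5) {
  rows <- lapply(seeds, function(s) {
    cfg <- .study_config(s, n_frames = 1L, frame_interval_s = 1,
                         kinetics_model = "constant",
                         partition_coefficient = partition_coefficient)
    sim <- simulate_dissolution_movie(cfg, keep_expected = FALSE)
    seg <- make_masks(get_frame(sim$stack, 1))
    data.frame(seed = s,
               jaccard = jaccard_index(seg$condensate_mask,
                                       sim$truth$true_condensate_mask))
  })
  do.call(rbind, rows)
}
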