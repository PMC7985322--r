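#' Simulation configuration for synthetic condensate movies
#'
#' Describes a single-cell scene: an elliptical cell footprint (optionally
#' with a nested nucleus) over a dark background, containing `n_droplets`
#' bright condensates (dense phase) on top of a uniform dilute pool. The
#' droplet excess intensity evolves in time according to `kinetics_model`,
#' and the lost (or gained) dense-phase integrated intensity is
#' redistributed uniformly into the dilute pool inside the cell, so the
#' total expected photon count is constant over time. Poisson shot noise
#' and Gaussian read noise are applied last.
#'
#' @param image_shape integer `(Y, X)` pixel dimensions.
#' @param n_frames number of frames.
#' @param frame_interval_s seconds between frames; frame `i` is acquired at
#'   `(i - 1) * frame_interval_s`.
#' @param cell_center,cell_semi_axes ellipse `(y, x)` center and `(a, b)`
#'   semi-axes (pixels) of the cell footprint. Defaults center the cell and
#'   use 80% of the half-extent.
#' @param nucleus_center,nucleus_semi_axes optional nested nucleus ellipse;
#'   `NULL` for none.
#' @param n_droplets number of condensates.
#' @param droplet_radius_px `(min, max)` radius range in pixels.
#' @param dilute_level expected photons/pixel inside the cell outside
#'   droplets at t = 0.
#' @param partition_coefficient ratio of dense-phase to dilute-phase
#'   expected intensity (> 1 for condensate-forming scenes).
#' @param dense_excess_level expected dense-phase excess photons/pixel at
#'   full droplet coverage; default `dilute_level * (partition_coefficient
#'   - 1)`. Supply explicitly for scenes with `dilute_level = 0` (all
#'   signal in droplets).
#' @param background_level expected photons/pixel outside the cell.
#' @param kinetics_model one of `"sigmoid_decay"`, `"exponential_decay"`,
#'   `"constant"`, `"sigmoid_growth"`.
#' @param tau_s characteristic time of the kinetics (seconds, > 0).
#' @param onset_s treatment-addition time t0 (seconds). Exponential decay
#'   starts exactly at `onset_s`; the sigmoid midpoint sits at
#'   `onset_s + sigmoid_midpoint_offset` (default `3 * tau_s`, so the
#'   transition is ~95% ahead at onset).
#' @param sigmoid_midpoint_offset seconds from onset to the logistic
#'   midpoint; `NULL` for the default `3 * tau_s`.
#' @param residual_fraction fraction of the initial droplet excess that
#'   survives at t = Inf (0 = complete dissolution). Setting
#'   `1 - residual_fraction` tunes the true disruption efficiency.
#' @param noise_gain photon scaling of Poisson shot noise: a pixel with
#'   expectation `e` is drawn as `gain * Poisson(e / gain)`. `0` disables
#'   shot noise.
#' @param read_noise_sd standard deviation of additive Gaussian read noise
#'   (0 disables). Negative pixel draws are clamped to 0.
#' @param acquisition_bleach_tau_s global acquisition photobleaching time
#'   constant applied to all cellular fluorescence (`Inf` = off, the
#'   default); provided to exercise normalizations that cancel it.
#' @param nuclear_droplet_fraction fraction of droplets placed inside the
#'   nucleus (requires a nucleus).
#' @param seed integer master seed; droplet placement and every per-frame
#'   noise stream derive from it, so identical config + seed gives
#'   bit-identical output.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(image_shape = c(96L, 96L),
                       n_frames = 60L,
                       frame_interval_s = 2,
                       cell_center = NULL,
                       cell_semi_axes = NULL,
                       nucleus_center = NULL,
                       nucleus_semi_axes = NULL,
                       n_droplets = 6L,
                       droplet_radius_px = c(3, 5),
                       dilute_level = 50,
                       partition_coefficient = 6,
                       dense_excess_level = NULL,
                       background_level = 10,
                       kinetics_model = "sigmoid_decay",
                       tau_s = 30,
                       onset_s = 60,
                       sigmoid_midpoint_offset = NULL,
                       residual_fraction = 0,
                       noise_gain = 1,
                       read_noise_sd = 2,
                       acquisition_bleach_tau_s = Inf,
                       nuclear_droplet_fraction = 0,
                       seed = 1L) {
  kinetics_model <- match.arg(
    kinetics_model,
    c("sigmoid_decay", "exponential_decay", "constant", "sigmoid_growth"))
  image_shape <- as.integer(image_shape)
  if (is.null(cell_center)) cell_center <- (image_shape + 1) / 2
  if (is.null(cell_semi_axes)) cell_semi_axes <- 0.4 * image_shape
  if (is.null(sigmoid_midpoint_offset)) sigmoid_midpoint_offset <- 3 * tau_s
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (onset_s < 0) stop("onset_s must be >= 0")
  if (dilute_level < 0 || background_level < 0) stop("levels must be >= 0")
  if (n_droplets > 0 && is.null(dense_excess_level) && partition_coefficient <= 1) {
    stop("partition_coefficient must be > 1 for condensate-forming scenes")
  }
  if (is.null(dense_excess_level)) {
    dense_excess_level <- dilute_level * (partition_coefficient - 1)
  }
  if (residual_fraction < 0 || residual_fraction > 1) {
    stop("residual_fraction must be in [0, 1]")
  }
  if (nuclear_droplet_fraction > 0 && is.null(nucleus_center)) {
    stop("nuclear droplets requested without a nucleus ellipse")
  }
  if (length(droplet_radius_px) == 1L) {
    droplet_radius_px <- rep(droplet_radius_px, 2L)
  }
  structure(
    list(image_shape = image_shape, n_frames = as.integer(n_frames),
         frame_interval_s = frame_interval_s,
         cell_center = cell_center, cell_semi_axes = cell_semi_axes,
         nucleus_center = nucleus_center, nucleus_semi_axes = nucleus_semi_axes,
         n_droplets = as.integer(n_droplets),
         droplet_radius_px = droplet_radius_px,
         dilute_level = dilute_level,
         partition_coefficient = partition_coefficient,
         dense_excess_level = dense_excess_level,
         background_level = background_level,
         kinetics_model = kinetics_model, tau_s = tau_s, onset_s = onset_s,
         sigmoid_midpoint_offset = sigmoid_midpoint_offset,
         residual_fraction = residual_fraction,
         noise_gain = noise_gain, read_noise_sd = read_noise_sd,
         acquisition_bleach_tau_s = acquisition_bleach_tau_s,
         nuclear_droplet_fraction = nuclear_droplet_fraction,
         seed = as.integer(seed)),
    class = "sim_config")
}

# deterministic, well-separated per-frame seed stream derived from the master
.frame_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483629)
}

.ellipse_mask <- function(shape, center, semi) {
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((y - center[1]) / semi[1])^2 + ((x - center[2]) / semi[2])^2 <= 1
}

# coverage fraction of each pixel by a disc (anti-aliased edge approximation)
.disc_coverage <- function(shape, center, r) {
  y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  x <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d <- sqrt((y - center[1])^2 + (x - center[2])^2)
  pmin(pmax(r + 0.5 - d, 0), 1)
}

# inside-the-ellipse check with a margin (negative margin shrinks the ellipse)
.in_ellipse <- function(p, center, semi, margin) {
  a <- semi[1] + margin; b <- semi[2] + margin
  if (a <= 0 || b <= 0) return(FALSE)
  ((p[1] - center[1]) / a)^2 + ((p[2] - center[2]) / b)^2 <= 1
}

#' Place non-overlapping droplets inside the cell (and nucleus quota)
#' @noRd
.place_droplets <- function(cfg, max_tries = 2000L) {
  n <- cfg$n_droplets
  if (n == 0L) return(data.frame(y = numeric(0), x = numeric(0), r = numeric(0)))
  n_nuc <- round(cfg$nuclear_droplet_fraction * n)
  placed <- data.frame(y = numeric(0), x = numeric(0), r = numeric(0))
  for (i in seq_len(n)) {
    in_nucleus <- i <= n_nuc
    r <- stats::runif(1, cfg$droplet_radius_px[1], cfg$droplet_radius_px[2])
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(stats::runif(1, 1, cfg$image_shape[1]),
             stats::runif(1, 1, cfg$image_shape[2]))
      if (in_nucleus) {
        fits <- .in_ellipse(p, cfg$nucleus_center, cfg$nucleus_semi_axes, -(r + 0.5))
      } else {
        fits <- .in_ellipse(p, cfg$cell_center, cfg$cell_semi_axes, -(r + 0.5))
        if (fits && !is.null(cfg$nucleus_center) && cfg$nuclear_droplet_fraction > 0) {
          # cytosolic droplets stay clear of the nucleus
          fits <- !.in_ellipse(p, cfg$nucleus_center, cfg$nucleus_semi_axes, r + 0.5)
        }
      }
      if (!fits) next
      if (nrow(placed) > 0) {
        dmin <- sqrt((placed$y - p[1])^2 + (placed$x - p[2])^2)
        if (any(dmin < placed$r + r + 1)) next
      }
      placed <- rbind(placed, data.frame(y = p[1], x = p[2], r = r))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("droplet placement failed after ", max_tries,
           " tries; reduce n_droplets or droplet_radius_px")
    }
  }
  placed
}

#' Closed-form excess-intensity profile
#'
#' Fraction of the initial droplet excess intensity remaining at time `t`
#' under each kinetics model. Sigmoid decay is a logistic
#' `1 / (1 + exp((t - t_mid) / tau))` with midpoint
#' `onset_s + sigmoid_midpoint_offset`; exponential decay is 1 before
#' `onset_s` and `exp(-(t - onset_s) / tau)` after; growth is the rising
#' logistic. A `residual_fraction` r rescales decay profiles to
#' `r + (1 - r) * f(t)`.
#'
#' @param t numeric times (seconds).
#' @param cfg a [sim_config()].
#' @return numeric vector in `[0, 1]`, same length as `t`.
#' @export
excess_profile <- function(t, cfg) {
  r <- cfg$residual_fraction
  f <- switch(cfg$kinetics_model,
    constant = rep(1, length(t)),
    sigmoid_decay = {
      tm <- cfg$onset_s + cfg$sigmoid_midpoint_offset
      1 / (1 + exp((t - tm) / cfg$tau_s))
    },
    exponential_decay = ifelse(t < cfg$onset_s, 1,
                               exp(-(t - cfg$onset_s) / cfg$tau_s)),
    sigmoid_growth = {
      tm <- cfg$onset_s + cfg$sigmoid_midpoint_offset
      1 / (1 + exp(-(t - tm) / cfg$tau_s))
    })
  r + (1 - r) * f
}

#' Scene geometry shared by all frames
#' @noRd
.build_scene <- function(cfg) {
  set.seed(cfg$seed)
  cell <- .ellipse_mask(cfg$image_shape, cfg$cell_center, cfg$cell_semi_axes)
  nucleus <- if (!is.null(cfg$nucleus_center)) {
    .ellipse_mask(cfg$image_shape, cfg$nucleus_center, cfg$nucleus_semi_axes)
  }
  droplets <- .place_droplets(cfg)
  coverage <- matrix(0, cfg$image_shape[1], cfg$image_shape[2])
  for (i in seq_len(nrow(droplets))) {
    coverage <- coverage + .disc_coverage(cfg$image_shape,
                                          c(droplets$y[i], droplets$x[i]),
                                          droplets$r[i])
  }
  coverage <- pmin(coverage, 1)
  list(cell = cell, nucleus = nucleus, droplets = droplets,
       coverage = coverage, cond_mask = coverage >= 0.5,
       a_cell = sum(cell))
}

#' Expected (noise-free) frame at excess factor f
#' @noRd
.expected_frame <- function(cfg, scene, f, bleach_factor = 1) {
  excess_px <- cfg$dense_excess_level
  e_tot <- sum(scene$coverage) * excess_px
  fluor <- scene$cell * (cfg$dilute_level + e_tot * (1 - f) / scene$a_cell) +
    scene$coverage * excess_px * f
  cfg$background_level + bleach_factor * fluor
}

.apply_noise <- function(expected, cfg, frame_index) {
  if (cfg$noise_gain <= 0 && cfg$read_noise_sd <= 0) return(expected)
  set.seed(.frame_seed(cfg$seed, frame_index))
  out <- expected
  if (cfg$noise_gain > 0) {
    out <- cfg$noise_gain * stats::rpois(length(expected),
                                         expected / cfg$noise_gain)
  }
  if (cfg$read_noise_sd > 0) {
    out <- out + stats::rnorm(length(expected), 0, cfg$read_noise_sd)
  }
  matrix(pmax(out, 0), nrow = nrow(expected))
}

# fraction of background-subtracted signal inside the true condensate mask,
# computed by direct arithmetic on an expected frame
.true_fraction <- function(frame, cond_mask, cell_mask, background) {
  v <- frame - background
  a_d <- sum(cond_mask)
  total <- sum(v[cell_mask])
  if (a_d == 0 || total <= 0) return(0)
  dilute <- cell_mask & !cond_mask
  fr <- a_d * (mean(v[cond_mask]) - mean(v[dilute])) / total
  max(fr, 0)
}

#' Simulate a condensate dissolution (or formation) movie
#'
#' Renders the expected scene per frame under the configured kinetics, with
#' the dense-phase excess redistributed into the dilute pool so the total
#' expected photon count is constant across frames, then applies Poisson
#' shot noise and Gaussian read noise. Ground truth (masks, per-frame true
#' condensate fraction, true tau, true efficiency) is returned alongside.
#'
#' @param config a [sim_config()] with a decay, growth or constant
#'   `kinetics_model`.
#' @param keep_expected store the noise-free expected frames in the ground
#'   truth (default TRUE).
#' @return A list with elements `stack` ([image_stack]) and `truth`
#'   (class `ground_truth`): `true_condensate_mask`, `true_cell_mask`,
#'   `true_nucleus_mask`, per-frame `true_fraction`, `true_tau_s`,
#'   `true_partition_coefficient`, `true_efficiency_percent` (decay models;
#'   pre = last frame before `onset_s`, post = final frame),
#'   `pre_frame`/`post_frame`, `excess_factor`, `seed` and, optionally,
#'   `expected`.
#' @export
simulate_dissolution_movie <- function(config, keep_expected = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  scene <- .build_scene(config)
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  f <- excess_profile(times, config)
  bleach <- if (is.finite(config$acquisition_bleach_tau_s)) {
    exp(-times / config$acquisition_bleach_tau_s)
  } else rep(1, config$n_frames)

  sh <- config$image_shape
  pixels <- array(0, c(sh[1], sh[2], config$n_frames))
  expected <- array(0, c(sh[1], sh[2], config$n_frames))
  frac <- numeric(config$n_frames)
  for (i in seq_len(config$n_frames)) {
    e <- .expected_frame(config, scene, f[i], bleach[i])
    expected[, , i] <- e
    frac[i] <- .true_fraction(e, scene$cond_mask, scene$cell, config$background_level)
    pixels[, , i] <- .apply_noise(e, config, i)
  }

  pre_frame <- max(1L, sum(times < config$onset_s))
  post_frame <- config$n_frames
  eff <- if (config$kinetics_model %in% c("sigmoid_decay", "exponential_decay") &&
             frac[pre_frame] > 0) {
    100 * (frac[pre_frame] - frac[post_frame]) / frac[pre_frame]
  } else NA_real_

  truth <- structure(
    list(true_condensate_mask = scene$cond_mask,
         true_cell_mask = scene$cell,
         true_nucleus_mask = scene$nucleus,
         coverage = scene$coverage,
         droplets = scene$droplets,
         true_fraction = frac,
         excess_factor = f,
         true_tau_s = config$tau_s,
         true_partition_coefficient = config$partition_coefficient,
         true_efficiency_percent = eff,
         pre_frame = pre_frame, post_frame = post_frame,
         times_s = times, seed = config$seed,
         expected = if (keep_expected) expected),
    class = "ground_truth")
  list(stack = image_stack(pixels, times), truth = truth)
}

#' Simulate a FRAP movie
#'
#' Renders a static condensate scene, bleaches `bleach_depth` of the
#' fluorescence inside `bleach_region` at `bleach_frame`, and lets the
#' region recover by molecular exchange with the unbleached pool with time
#' constant `exchange_tau_s`. The recovery amplitude accounts for the
#' bleach-depleted pool, so the normalized FRAP trace (see
#' [normalize_frap()]) plateaus exactly at `mobile_fraction`. Signal drawn
#' into the region during recovery is removed uniformly from the rest of
#' the cell, conserving the post-bleach total.
#'
#' @param config a [sim_config()]; its kinetics are ignored (held constant).
#' @param bleach_frame frame index at which the bleach pulse lands (> 1).
#' @param bleach_region optional logical mask of the bleached region; the
#'   default is a disc of half the radius centered on the first droplet.
#' @param bleach_depth fraction of the region's fluorescence destroyed
#'   (`[0, 1]`; instrument calibrations typically keep this at 0.60-0.85).
#' @param mobile_fraction fraction of the region's molecules free to
#'   exchange with the pool.
#' @param exchange_tau_s exchange time constant (seconds); `0` means
#'   instantaneous recovery from the first post-bleach frame.
#' @param keep_expected store noise-free frames in the ground truth.
#' @return A list with `stack`, and `truth` carrying masks,
#'   `bleach_region`, `bleach_frame`, `true_mobile_fraction`,
#'   `true_exchange_tau_s`, `true_bleach_depth` and the closed-form
#'   `expected_normalized` trace.
#' @export
simulate_frap_movie <- function(config, bleach_frame, bleach_region = NULL,
                                bleach_depth = 0.7, mobile_fraction = 0.5,
                                exchange_tau_s = 30, keep_expected = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (bleach_depth < 0 || bleach_depth > 1) stop("bleach_depth must be in [0, 1]")
  if (bleach_frame < 2L || bleach_frame > config$n_frames) {
    stop("bleach_frame must leave at least one pre-bleach frame and be in range")
  }
  scene <- .build_scene(config)
  if (is.null(bleach_region)) {
    if (nrow(scene$droplets) == 0L) stop("no droplet to bleach")
    bleach_region <- .disc_coverage(config$image_shape,
                                    c(scene$droplets$y[1], scene$droplets$x[1]),
                                    scene$droplets$r[1] / 2) >= 0.5
  }
  stopifnot(identical(dim(bleach_region), dim(scene$cell)))
  if (any(bleach_region & !scene$cell)) stop("bleach_region outside the cell")

  times <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  base <- .expected_frame(config, scene, 1)
  fluor <- base - config$background_level
  i_region <- sum(fluor[bleach_region])
  t_total <- sum(fluor[scene$cell])
  b_lost <- bleach_depth * i_region
  r_max <- mobile_fraction * b_lost * (1 - i_region / t_total)
  rest <- scene$cell & !bleach_region
  a_rest <- sum(rest)

  sh <- config$image_shape
  pixels <- array(0, c(sh[1], sh[2], config$n_frames))
  expected <- array(0, c(sh[1], sh[2], config$n_frames))
  norm_exp <- numeric(config$n_frames)
  t_bleach <- times[bleach_frame]
  for (i in seq_len(config$n_frames)) {
    e <- base
    if (i >= bleach_frame) {
      dt <- times[i] - t_bleach
      rec <- if (exchange_tau_s <= 0) {
        if (dt > 0) r_max else 0
      } else r_max * (1 - exp(-dt / exchange_tau_s))
      fl <- fluor
      fl[bleach_region] <- fl[bleach_region] *
        (i_region - b_lost + rec) / i_region
      fl[rest] <- fl[rest] - rec / a_rest
      e <- config$background_level + fl
      norm_exp[i] <- rec / (b_lost * (1 - i_region / t_total))
    } else {
      norm_exp[i] <- 1
    }
    expected[, , i] <- e
    pixels[, , i] <- .apply_noise(e, config, i)
  }

  truth <- structure(
    list(true_condensate_mask = scene$cond_mask,
         true_cell_mask = scene$cell,
         bleach_region = bleach_region,
         bleach_frame = bleach_frame,
         true_mobile_fraction = mobile_fraction,
         true_exchange_tau_s = exchange_tau_s,
         true_bleach_depth = bleach_depth,
         expected_normalized = norm_exp,
         times_s = times, seed = config$seed,
         expected = if (keep_expected) expected),
    class = "ground_truth")
  list(stack = image_stack(pixels, times), truth = truth)
}

#' Simulate a matched endpoint image pair (condensates vs blocked)
#'
#' Renders two single-frame scenes with identical cell geometry — one
#' forming condensates, one "blocked" (fewer or no droplets, or a reduced
#' partition coefficient) — for endpoint condensate-intensity-ratio
#' comparisons. The two configurations should carry the same total
#' expected cell fluorescence; a mismatch beyond 1% is flagged.
#'
#' @param config_droplets,config_blocked two [sim_config()]s with identical
#'   `image_shape` and cell ellipse.
#' @return A list with `stack_droplets`, `stack_blocked` and `truth`
#'   containing per-scene true condensate intensity ratios
#'   (`true_ratio_droplets`, `true_ratio_blocked`) and masks.
#' @export
simulate_blocking_endpoint <- function(config_droplets, config_blocked) {
  stopifnot(inherits(config_droplets, "sim_config"),
            inherits(config_blocked, "sim_config"))
  if (!identical(config_droplets$image_shape, config_blocked$image_shape) ||
      !isTRUE(all.equal(config_droplets$cell_center, config_blocked$cell_center)) ||
      !isTRUE(all.equal(config_droplets$cell_semi_axes, config_blocked$cell_semi_axes))) {
    stop("mismatched cell geometry between the two configurations")
  }
  render_one <- function(cfg) {
    scene <- .build_scene(cfg)
    e <- .expected_frame(cfg, scene, 1)
    v <- e - cfg$background_level
    total <- sum(v[scene$cell])
    ratio <- if (any(scene$cond_mask)) sum(v[scene$cond_mask]) / total else 0
    list(scene = scene, expected = e,
         pixels = .apply_noise(e, cfg, 1L), ratio = ratio, total = total)
  }
  a <- render_one(config_droplets)
  b <- render_one(config_blocked)
  if (abs(a$total - b$total) > 0.01 * max(a$total, b$total)) {
    warning("total expected cell fluorescence differs by > 1% between scenes")
  }
  truth <- structure(
    list(true_ratio_droplets = a$ratio, true_ratio_blocked = b$ratio,
         true_cell_mask = a$scene$cell,
         true_condensate_mask_droplets = a$scene$cond_mask,
         true_condensate_mask_blocked = b$scene$cond_mask,
         expected_droplets = a$expected, expected_blocked = b$expected,
         seed = config_droplets$seed),
    class = "ground_truth")
  list(stack_droplets = image_stack(a$pixels, 0),
       stack_blocked = image_stack(b$pixels, 0),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
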