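#' Condensate signal timecourse from a segmented movie
#'
#' Per-frame condensate observable for kinetics fitting: either the
#' background-subtracted integrated excess intensity
#' `Area_dense * (MeanI_dense - MeanI_dilute)` (default, the quantity
#' whose decay the dissolution fits describe) or the condensate
#' `fraction` of total signal. Frames with empty condensate masks yield 0
#' (not missing) and are flagged.
#'
#' For kinetics the condensate footprint should be held fixed at the
#' pre-treatment segmentation (pass a single `segmentation`): re-applying
#' a threshold to each frame of a dissolving movie shrinks the mask and
#' conflates area loss with intensity loss, biasing tau low.
#'
#' @param stack an [image_stack].
#' @param segs a single `segmentation` (measured on every frame — the
#'   fixed-footprint convention) or a list of `segmentation`s, one per
#'   frame (see [segment_stack()]).
#' @param background scalar or per-frame vector of background intensities.
#' @param observable `"integrated_excess"` or `"fraction"`.
#' @param onset_s treatment-addition time carried along for fitting.
#' @return A `timecourse`: `times_s`, `values`, `observable`, `onset_s`,
#'   `n_empty` (count of empty-mask frames).
#' @export
condensate_timecourse <- function(stack, segs, background = 0,
                                  observable = c("integrated_excess", "fraction"),
                                  onset_s = 0) {
  stopifnot(inherits(stack, "image_stack"))
  if (inherits(segs, "segmentation")) segs <- rep(list(segs), stack$n_frames)
  stopifnot(length(segs) == stack$n_frames)
  if (stack$n_frames < 3L) stop("need at least 3 frames for a timecourse")
  observable <- match.arg(observable)
  bg <- rep_len(background, stack$n_frames)
  vals <- numeric(stack$n_frames)
  n_empty <- 0L
  for (i in seq_len(stack$n_frames)) {
    m <- partition_stats(get_frame(stack, i), segs[[i]], bg[i])
    if (m$empty_condensate) n_empty <- n_empty + 1L
    vals[i] <- if (observable == "fraction") m$fraction_in_condensate else {
      if (m$empty_condensate) 0 else m$area_dense * (m$mean_dense - m$mean_dilute)
    }
  }
  if (n_empty == stack$n_frames) warning("all frames have empty condensate masks")
  structure(list(times_s = stack$times_s, values = vals,
                 observable = observable, onset_s = onset_s,
                 n_empty = n_empty),
            class = "timecourse")
}

#' Build a timecourse from raw vectors
#'
#' @param times_s strictly increasing times (seconds).
#' @param values condensate signal per frame.
#' @param onset_s treatment-addition time.
#' @param observable label for the value column.
#' @return A `timecourse`.
#' @export
timecourse <- function(times_s, values, onset_s = 0,
                       observable = "integrated_excess") {
  stopifnot(length(times_s) == length(values), all(diff(times_s) > 0))
  structure(list(times_s = as.numeric(times_s), values = as.numeric(values),
                 observable = observable, onset_s = onset_s, n_empty = 0L),
            class = "timecourse")
}

.no_fit <- function(model, reason) {
  structure(list(model = model, base = NA_real_, amplitude = NA_real_,
                 t_half_s = NA_real_, t_start_s = NA_real_, tau_s = NA_real_,
                 r_squared = NA_real_, converged = FALSE,
                 param_uncertainties = NULL, reason = reason),
            class = "kinetic_fit")
}

.fit_result <- function(model, fit, t, v, extra = list()) {
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(co)))
  pred <- stats::predict(fit)
  ss_res <- sum((v - pred)^2)
  ss_tot <- sum((v - mean(v))^2)
  out <- list(model = model,
              base = unname(co["base"]), amplitude = unname(co["amplitude"]),
              t_half_s = unname(co["t_half"]), t_start_s = extra$t_start_s,
              tau_s = unname(co["tau"]),
              r_squared = 1 - ss_res / ss_tot,
              converged = is.finite(co["tau"]) && co["tau"] > 0,
              param_uncertainties = se, reason = NULL)
  structure(out, class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("kinetic_fit (%s): not converged (%s)\n", x$model,
                x$reason %||% "optimizer failure"))
    return(invisible(x))
  }
  mid <- if (x$model == "sigmoid") sprintf("t_half=%.4g s", x$t_half_s) else
    sprintf("t_start=%.4g s", x$t_start_s)
  cat(sprintf("kinetic_fit (%s): tau=%.4g s, base=%.4g, amplitude=%.4g, %s, R2=%.4f\n",
              x$model, x$tau_s, x$base, x$amplitude, mid, x$r_squared))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a sigmoid dissolution curve
#'
#' Least-squares fit of the logistic
#' \deqn{v(t) = base + amplitude / (1 + exp((t - t_{half}) / \tau))}
#' (decreasing past `t_half` for positive amplitude); `tau_s` is the
#' characteristic time. Initialization is derivative-free: base and
#' amplitude from the series extremes, `t_half` from the half-crossing
#' time, tau from the 25-75% crossing span divided by `2 log 3`. The
#' optimizer is bounded Levenberg-Marquardt least squares with `tau > 0`
#' (relative tolerance 1e-8, up to 1000 iterations). Non-convergence is
#' returned as `converged = FALSE`, never a fabricated tau.
#'
#' @param tc a [timecourse()] with >= 6 points spanning the transition.
#' @param init optional named list overriding starting values
#'   (`base`, `amplitude`, `t_half`, `tau`).
#' @return A `kinetic_fit`.
#' @export
fit_sigmoid <- function(tc, init = NULL) {
  stopifnot(inherits(tc, "timecourse"))
  t <- tc$times_s; v <- tc$values
  if (length(t) < 6L) return(.no_fit("sigmoid", "fewer than 6 points"))
  if (stats::sd(v) == 0) return(.no_fit("sigmoid", "zero-variance series"))

  lo <- min(v); hi <- max(v)
  decreasing <- stats::cor(t, v) < 0
  crossing <- function(level) {
    s <- if (decreasing) -v else v
    lvl <- if (decreasing) -level else level
    i <- which(s >= lvl)[1]
    if (is.na(i) || i == 1L) return(t[1])
    # linear interpolation between the bracketing samples
    t[i - 1] + (t[i] - t[i - 1]) * (lvl - s[i - 1]) / (s[i] - s[i - 1])
  }
  t25 <- crossing(lo + 0.25 * (hi - lo))
  t50 <- crossing(lo + 0.50 * (hi - lo))
  t75 <- crossing(lo + 0.75 * (hi - lo))
  tau0 <- max(abs(t75 - t25) / (2 * log(3)), diff(range(t)) / 100)
  start <- list(base = lo, amplitude = if (decreasing) hi - lo else lo - hi,
                t_half = t50, tau = tau0)
  if (!is.null(init)) start[names(init)] <- init

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ base + amplitude / (1 + exp((t - t_half) / tau)),
      start = start,
      lower = c(base = -Inf, amplitude = -Inf, t_half = -Inf, tau = 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) return(.no_fit("sigmoid", "optimizer failure"))
  .fit_result("sigmoid", fit, t, v)
}

#' Fit an exponential dissolution curve
#'
#' Least-squares fit of
#' \deqn{v(t) = base + amplitude \exp(-(t - t_{start}) / \tau)}
#' restricted to points at `t >= t_start_s` (frames before treatment
#' addition are excluded). `tau_s` is the characteristic time.
#'
#' @param tc a [timecourse()].
#' @param t_start_s time origin of the decay (e.g. the treatment-addition
#'   time); defaults to `tc$onset_s`.
#' @param init optional named list overriding starting values
#'   (`base`, `amplitude`, `tau`).
#' @return A `kinetic_fit`.
#' @export
fit_exponential <- function(tc, t_start_s = NULL, init = NULL) {
  stopifnot(inherits(tc, "timecourse"))
  t_start_s <- t_start_s %||% tc$onset_s
  keep <- tc$times_s >= t_start_s
  t <- tc$times_s[keep]; v <- tc$values[keep]
  if (length(t) < 4L) return(.no_fit("exponential", "fewer than 4 points after t_start"))
  if (stats::sd(v) == 0) return(.no_fit("exponential", "zero-variance series"))

  base0 <- mean(v[t >= stats::quantile(t, 0.8)])
  amp0 <- v[1] - base0
  # log-linear slope for the initial tau guess
  w <- (v - base0) / amp0
  pos <- which(w > 0.05)
  tau0 <- if (length(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(w[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  start <- list(base = base0, amplitude = amp0, tau = max(tau0, 1e-6))
  if (!is.null(init)) start[names(init)] <- init

  ts <- t - t_start_s
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ base + amplitude * exp(-ts / tau),
      start = start,
      lower = c(base = -Inf, amplitude = -Inf, tau = 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) return(.no_fit("exponential", "optimizer failure"))
  .fit_result("exponential", fit, t, v, extra = list(t_start_s = t_start_s))
}

#' Fold change between two characteristic times
#'
#' `tau_a / tau_b` with first-order uncertainty propagation from the
#' per-parameter standard errors.
#'
#' @param fit_a,fit_b converged `kinetic_fit`s.
#' @return List with `fold`, `se` (NA when either tau uncertainty is
#'   unavailable).
#' @export
compare_taus <- function(fit_a, fit_b) {
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    stop("both fits must have converged")
  }
  fold <- fit_a$tau_s / fit_b$tau_s
  sa <- fit_a$param_uncertainties["tau"]
  sb <- fit_b$param_uncertainties["tau"]
  se <- if (is.finite(sa) && is.finite(sb)) {
    fold * sqrt((sa / fit_a$tau_s)^2 + (sb / fit_b$tau_s)^2)
  } else NA_real_
  list(fold = fold, se = unname(se))
}
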