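#' Raw FRAP trace
#'
#' Per-frame integrated density of the bleached region and of the whole
#' cell (background-free). The region mask is drawn at the bleach frame
#' and held fixed.
#'
#' @param times_s frame times (seconds), strictly increasing.
#' @param raw_bleach_integrated integrated intensity over the bleached
#'   region per frame.
#' @param raw_total_integrated background-free whole-cell integrated
#'   intensity per frame (> 0 everywhere).
#' @param bleach_index frame index of the bleach pulse (> 1, so at least
#'   one pre-bleach frame exists).
#' @return A `frap_trace` (unnormalized; see [normalize_frap()]).
#' @export
frap_trace <- function(times_s, raw_bleach_integrated, raw_total_integrated,
                       bleach_index) {
  n <- length(times_s)
  stopifnot(length(raw_bleach_integrated) == n,
            length(raw_total_integrated) == n,
            all(diff(times_s) > 0))
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > n) {
    stop("bleach_index must be > 1 and within the trace")
  }
  if (any(raw_total_integrated <= 0)) {
    stop("total integrated density must be > 0 at every frame")
  }
  structure(list(times_s = as.numeric(times_s),
                 raw_bleach_integrated = as.numeric(raw_bleach_integrated),
                 raw_total_integrated = as.numeric(raw_total_integrated),
                 bleach_index = bleach_index, normalized = NULL),
            class = "frap_trace")
}

#' Measure a FRAP trace from a movie
#'
#' Sums background-subtracted intensity over the fixed bleached-region
#' mask and over the whole cell mask at every frame.
#'
#' @param stack an [image_stack].
#' @param bleach_region,cell_mask logical masks.
#' @param bleach_index bleach frame index.
#' @param background scalar background intensity.
#' @return A `frap_trace`.
#' @export
measure_frap <- function(stack, bleach_region, cell_mask, bleach_index,
                         background = 0) {
  stopifnot(inherits(stack, "image_stack"))
  reg <- vapply(seq_len(stack$n_frames), function(i) {
    f <- get_frame(stack, i) - background
    sum(f[bleach_region])
  }, numeric(1))
  tot <- vapply(seq_len(stack$n_frames), function(i) {
    f <- get_frame(stack, i) - background
    sum(f[cell_mask])
  }, numeric(1))
  frap_trace(stack$times_s, reg, tot, bleach_index)
}

#' Normalize a FRAP trace to the [0, 1] recovery scale
#'
#' The region integrated density is first normalized to the background-free
#' total cell integrated density (cancelling global acquisition
#' photobleaching), giving `r(t)`; the curve is then mapped so that the
#' bleach time point is 0 and the pre-bleach average is 1:
#' \deqn{normalized(t) = (r(t) - r(t_{bleach})) / (\bar r_{pre} - r(t_{bleach})).}
#' Post-bleach overshoot above 1 is left unclipped. A warning (class
#' `condensr_bleach_depth`) is raised when the apparent bleach depth falls
#' outside the 60-85% calibration band typical of instrument setups.
#'
#' @param trace a `frap_trace`.
#' @return The trace with `normalized` filled in and `apparent_depth`
#'   (fraction of the region ratio lost at the bleach frame) attached.
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  r <- trace$raw_bleach_integrated / trace$raw_total_integrated
  pre <- mean(r[seq_len(trace$bleach_index - 1L)])
  r0 <- r[trace$bleach_index]
  if (pre == r0) stop("no bleaching detected: pre-bleach mean equals bleach-frame value")
  trace$normalized <- (r - r0) / (pre - r0)
  trace$apparent_depth <- 1 - r0 / pre
  if (trace$apparent_depth < 0.60 || trace$apparent_depth > 0.85) {
    warning(structure(
      class = c("condensr_bleach_depth", "warning", "condition"),
      list(message = sprintf(
        "apparent bleach depth %.2f outside the 0.60-0.85 calibration band",
        trace$apparent_depth),
        call = sys.call(-1))))
  }
  trace
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("frap_trace: %d frames, bleach at frame %d (t=%g s)%s\n",
              length(x$times_s), x$bleach_index, x$times_s[x$bleach_index],
              if (is.null(x$normalized)) " [raw]" else
                sprintf(", apparent depth %.2f", x$apparent_depth)))
  invisible(x)
}

#' Normalized recovery at a given time after the bleach
#'
#' Linear interpolation of the normalized trace at
#' `t_bleach + elapsed_s`.
#'
#' @param trace a normalized `frap_trace`.
#' @param elapsed_s seconds after the bleach pulse; must lie within the
#'   post-bleach span of the trace.
#' @return Normalized recovery fraction.
#' @export
recovery_at <- function(trace, elapsed_s) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$normalized)) stop("trace is not normalized; call normalize_frap()")
  target <- trace$times_s[trace$bleach_index] + elapsed_s
  if (elapsed_s < 0 || target > trace$times_s[length(trace$times_s)]) {
    stop("elapsed_s outside the post-bleach span of the trace")
  }
  stats::approx(trace$times_s, trace$normalized, xout = target)$y
}

#' Single-exponential fit of a normalized FRAP recovery
#'
#' Convenience summary beyond the plain normalized curve: fits
#' `norm(t) = plateau - plateau * exp(-(t - t_bleach)/tau)` to the
#' post-bleach trace via [fit_exponential()], returning the mobile
#' fraction (plateau) and exchange half-time.
#'
#' @param trace a normalized `frap_trace`.
#' @return List with `mobile_fraction`, `exchange_tau_s`, `half_time_s`,
#'   and the underlying `fit`.
#' @export
fit_frap_recovery <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  if (is.null(trace$normalized)) stop("normalize the trace first")
  post <- seq(trace$bleach_index, length(trace$times_s))
  tc <- timecourse(trace$times_s[post], trace$normalized[post],
                   onset_s = trace$times_s[trace$bleach_index],
                   observable = "normalized_recovery")
  fit <- fit_exponential(tc, t_start_s = tc$onset_s)
  if (!fit$converged) {
    return(list(mobile_fraction = NA_real_, exchange_tau_s = NA_real_,
                half_time_s = NA_real_, fit = fit))
  }
  list(mobile_fraction = fit$base, exchange_tau_s = fit$tau_s,
       half_time_s = log(2) * fit$tau_s, fit = fit)
}
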