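#' Histogram for threshold search
#'
#' 256 bins (by default) spanning the per-image `[min, max]` range, the
#' convention ImageJ's auto-threshold methods use on 8-bit-like data.
#' Candidate thresholds are the interior bin edges; a pixel is foreground
#' when strictly greater than the threshold.
#'
#' @noRd
.threshold_histogram <- function(image, n_bins) {
  v <- as.numeric(image)
  if (length(v) == 0L) stop("empty image")
  if (!all(is.finite(v))) stop("image contains non-finite values")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate histogram: image is constant")
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, edges = edges, mids = (edges[-1L] + edges[-(n_bins + 1L)]) / 2)
}

#' Otsu threshold
#'
#' Returns the bin-edge threshold maximizing the between-class variance
#' \eqn{w_0 w_1 (\mu_0 - \mu_1)^2} over a `n_bins` histogram spanning the
#' image's `[min, max]` range. Ties are broken toward the lower threshold.
#'
#' @param image numeric matrix/array of intensities with at least two
#'   distinct values.
#' @param n_bins histogram bin count (default 256).
#' @return Scalar threshold; pixels strictly greater are foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  h <- .threshold_histogram(image, n_bins)
  p <- h$counts / sum(h$counts)
  w0 <- cumsum(p)                      # background = bins 1..k
  m  <- cumsum(p * h$mids)
  mt <- m[n_bins]
  k <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[k]
  # between-class variance; empty-class candidates contribute 0
  num <- (mt * w0[k] - m[k])^2
  sigma_b <- ifelse(w0[k] > 0 & w1 > 0, num / (w0[k] * w1), 0)
  best <- which.max(sigma_b)           # first maximum = lower threshold
  h$edges[best + 1L]
}

#' Maximum-entropy (Kapur) threshold
#'
#' Returns the bin-edge threshold maximizing the sum of Shannon entropies
#' of the background and foreground class-conditional histograms.
#' Candidates leaving either class empty are skipped; ties break toward
#' the lower threshold.
#'
#' @inheritParams otsu_threshold
#' @return Scalar threshold; pixels strictly greater are foreground.
#' @export
maxentropy_threshold <- function(image, n_bins = 256L) {
  h <- .threshold_histogram(image, n_bins)
  p <- h$counts / sum(h$counts)
  P <- cumsum(p)
  # entropy accumulators: sum p log p over bins 1..k and k+1..n
  plogp <- ifelse(p > 0, p * log(p), 0)
  S <- cumsum(plogp)
  St <- S[n_bins]
  k <- seq_len(n_bins - 1L)
  Pb <- P[k]; Pf <- 1 - Pb
  Hb <- ifelse(Pb > 0, log(Pb) - S[k] / Pb, -Inf)
  Hf <- ifelse(Pf > 0, log(Pf) - (St - S[k]) / Pf, -Inf)
  obj <- Hb + Hf
  if (!any(is.finite(obj))) stop("degenerate histogram: no valid split")
  best <- which.max(obj)
  h$edges[best + 1L]
}

#' Mean threshold
#'
#' The arithmetic mean intensity of the image (ImageJ's "Mean"
#' auto-threshold), used for whole-cell masks where the cell occupies a
#' minority of a dark field.
#'
#' @param image numeric matrix/array of intensities, nonempty.
#' @return Scalar threshold; pixels strictly greater are foreground.
#' @export
mean_threshold <- function(image) {
  v <- as.numeric(image)
  if (length(v) == 0L) stop("empty image")
  mean(v)
}
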