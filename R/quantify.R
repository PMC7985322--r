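#' Estimate camera background from non-cell pixels
#'
#' Mean intensity over pixels outside the cell mask dilated by a small
#' margin (to keep dim cell-edge pixels out of the estimate).
#'
#' @param frame numeric matrix `[y, x]`.
#' @param cell_mask logical matrix; TRUE inside the cell.
#' @param dilate_px dilation radius applied to the cell mask before taking
#'   the complement (default 3).
#' @return Scalar background intensity.
#' @export
estimate_background <- function(frame, cell_mask, dilate_px = 3L) {
  stopifnot(identical(dim(frame), dim(cell_mask)))
  grown <- if (dilate_px > 0 && any(cell_mask)) {
    EBImage::dilate(cell_mask * 1, EBImage::makeBrush(2L * dilate_px + 1L, "disc")) > 0
  } else cell_mask > 0
  outside <- !grown
  if (!any(outside)) {
    stop("cell mask covers the entire frame; supply an explicit background value")
  }
  mean(frame[outside])
}

#' Dense/dilute partition statistics for one frame
#'
#' Background-subtracts the frame, then computes the dense-phase area, the
#' mean intensities of the dense phase (condensate mask) and dilute phase
#' (cell mask minus condensate mask), the total cell integrated density,
#' and the fraction of total signal held in condensates:
#' \deqn{fraction = Area_{dense} (MeanI_{dense} - MeanI_{dilute}) / TotalIntegratedDensity.}
#'
#' An empty condensate mask gives `area_dense = 0`, `fraction = 0` and
#' `mean_dense = NA` with `empty_condensate = TRUE` (flagged, not an
#' error).
#'
#' @param frame numeric matrix `[y, x]`.
#' @param seg a `segmentation` from [make_masks()], or any list with
#'   logical `condensate_mask` and `cell_mask`.
#' @param background scalar background intensity subtracted from every
#'   pixel before aggregation (see [estimate_background()]).
#' @return A `partition_measurement` object: `area_dense`, `mean_dense`,
#'   `mean_dilute`, `total_integrated_density`, `fraction_in_condensate`,
#'   `empty_condensate`.
#' @export
partition_stats <- function(frame, seg, background = 0) {
  cond <- seg$condensate_mask; cell <- seg$cell_mask
  stopifnot(identical(dim(frame), dim(cell)), background >= 0)
  if (!any(cell)) stop("empty cell mask")
  v <- frame - background
  total <- sum(v[cell])
  area_dense <- sum(cond)
  dilute <- cell & !cond
  mean_dilute <- if (any(dilute)) mean(v[dilute]) else NA_real_
  if (area_dense == 0L) {
    m <- list(area_dense = 0L, mean_dense = NA_real_, mean_dilute = mean_dilute,
              total_integrated_density = total, fraction_in_condensate = 0,
              empty_condensate = TRUE)
    return(structure(m, class = "partition_measurement"))
  }
  if (total <= 0) {
    stop("total integrated density <= 0; condensate fraction undefined")
  }
  mean_dense <- mean(v[cond])
  fraction <- area_dense * (mean_dense - mean_dilute) / total
  structure(
    list(area_dense = area_dense, mean_dense = mean_dense,
         mean_dilute = mean_dilute, total_integrated_density = total,
         fraction_in_condensate = fraction, empty_condensate = FALSE),
    class = "partition_measurement")
}

#' @export
print.partition_measurement <- function(x, ...) {
  cat(sprintf(
    "partition: area_dense=%d px, mean_dense=%.4g, mean_dilute=%.4g, total=%.6g, fraction=%.4f\n",
    x$area_dense, x$mean_dense, x$mean_dilute,
    x$total_integrated_density, x$fraction_in_condensate))
  invisible(x)
}

#' Percent disruption efficiency between pre- and post-treatment frames
#'
#' `100 * (Fraction_pre - Fraction_post) / Fraction_pre`, together with the
#' pre-treatment dense/dilute mean-intensity ratio. Negative efficiencies
#' (condensate growth) are reported, not clipped, and flagged via `grew`.
#'
#' @param pre,post `partition_measurement`s for the pre- and post-treatment
#'   frames.
#' @return A `disruption_result`: `fraction_pre`, `fraction_post`,
#'   `efficiency_percent`, `dense_dilute_ratio` (from the pre
#'   measurement), `grew`.
#' @export
disruption_efficiency <- function(pre, post) {
  fp <- pre$fraction_in_condensate
  if (!is.finite(fp) || fp <= 0) {
    stop("fraction_pre <= 0: disruption efficiency undefined")
  }
  fq <- post$fraction_in_condensate
  eff <- 100 * (fp - fq) / fp
  ratio <- if (is.finite(pre$mean_dense) && is.finite(pre$mean_dilute) &&
               pre$mean_dilute > 0) pre$mean_dense / pre$mean_dilute else NA_real_
  structure(
    list(fraction_pre = fp, fraction_post = fq, efficiency_percent = eff,
         dense_dilute_ratio = ratio, grew = eff < 0),
    class = "disruption_result")
}

#' @export
print.disruption_result <- function(x, ...) {
  cat(sprintf(
    "disruption: pre=%.4f post=%.4f efficiency=%.1f%% dense/dilute=%.3g%s\n",
    x$fraction_pre, x$fraction_post, x$efficiency_percent,
    x$dense_dilute_ratio, if (isTRUE(x$grew)) " [grew]" else ""))
  invisible(x)
}

#' Condensate intensity ratio
#'
#' Integrated background-subtracted intensity inside the condensate mask
#' divided by the total cell integrated density (background-subtracted).
#' Applied to a merged multi-cell field this is the field-level aggregate.
#'
#' @inheritParams partition_stats
#' @return Scalar in `[0, 1]` (0 for an empty condensate mask).
#' @export
condensate_intensity_ratio <- function(frame, seg, background = 0) {
  cond <- seg$condensate_mask; cell <- seg$cell_mask
  stopifnot(identical(dim(frame), dim(cell)))
  if (!any(cell)) stop("empty cell mask")
  v <- frame - background
  total <- sum(v[cell])
  if (total <= 0) stop("total integrated density <= 0; ratio undefined")
  if (!any(cond)) return(0)
  sum(v[cond]) / total
}

#' Linear relation between disruption efficiency and dense/dilute ratio
#'
#' Ordinary least-squares line of `efficiency_percent` against
#' `dense_dilute_ratio` over a cohort of cells, plus the Pearson
#' correlation — the per-cell relation whereby condensates with lower
#' dense/dilute ratios are disrupted more effectively.
#'
#' @param results list of `disruption_result`s (>= 3 with finite values).
#' @return List with `slope`, `intercept`, `pearson_r`, `n`.
#' @export
efficiency_ratio_correlation <- function(results) {
  eff <- vapply(results, function(r) r$efficiency_percent, numeric(1))
  ratio <- vapply(results, function(r) r$dense_dilute_ratio, numeric(1))
  ok <- is.finite(eff) & is.finite(ratio)
  if (sum(ok) < 3L) stop("need >= 3 results with finite efficiency and ratio")
  eff <- eff[ok]; ratio <- ratio[ok]
  if (stats::var(ratio) == 0) stop("zero variance in dense/dilute ratio")
  fit <- stats::lm(eff ~ ratio)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(ratio, eff),
       n = length(eff))
}

#' Percent uptake relative to untransfected cells
#'
#' Background-subtracted mean marker intensity (e.g. labelled transferrin)
#' in transfected cells expressed as a percent of the mean in
#' untransfected cells.
#'
#' @param transfected_intensities,untransfected_intensities numeric vectors
#'   of per-cell intensities.
#' @param background scalar background intensity.
#' @return Percent (100 = identical populations).
#' @export
uptake_percent <- function(transfected_intensities, untransfected_intensities,
                           background = 0) {
  if (!length(transfected_intensities) || !length(untransfected_intensities)) {
    stop("both intensity vectors must be nonempty")
  }
  denom <- mean(untransfected_intensities) - background
  if (denom <= 0) stop("untransfected mean <= background; percent undefined")
  100 * (mean(transfected_intensities) - background) / denom
}
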