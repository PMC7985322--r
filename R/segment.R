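#' Remove connected components smaller than a pixel count
#' @noRd
.remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow = nrow(mask))
}

.threshold_fun <- function(method) {
  switch(match.arg(method, c("otsu", "maxentropy", "mean")),
         otsu = otsu_threshold,
         maxentropy = maxentropy_threshold,
         mean = function(x, ...) mean_threshold(x))
}

#' Segment one frame into cell and condensate masks
#'
#' Reproduces the standard intensity-threshold segmentation of condensate
#' images: the cell mask is `pixels > cell threshold` (Mean method by
#' default), morphologically closed and hole-filled; the condensate mask is
#' `pixels > condensate threshold` (Otsu or maximum-entropy) restricted to
#' the cell mask, with objects smaller than `min_object_px` removed.
#'
#' A precomputed `condensate_threshold` can be supplied to hold a fixed
#' reference threshold across a timelapse (see [segment_stack()]).
#'
#' @param frame numeric matrix `[y, x]`.
#' @param condensate_method `"otsu"` or `"maxentropy"`.
#' @param cell_method `"mean"` (or either histogram method).
#' @param min_object_px smallest condensate object kept, in pixels
#'   (default 4, suppressing single-pixel shot noise).
#' @param condensate_threshold optional fixed threshold overriding the
#'   per-frame computation.
#' @param cell_mask optional precomputed logical cell mask (e.g. from a
#'   reference frame or ground truth); skips cell thresholding.
#' @return A `segmentation` object: logical `condensate_mask` and
#'   `cell_mask`, the `threshold_value` used for condensates, the
#'   `cell_threshold` (NA when a mask was supplied), `method`,
#'   `min_object_px`, and `empty_cell` flag.
#' @export
make_masks <- function(frame, condensate_method = "otsu", cell_method = "mean",
                       min_object_px = 4L, condensate_threshold = NULL,
                       cell_mask = NULL) {
  stopifnot(is.matrix(frame))
  cell_thr <- NA_real_
  if (is.null(cell_mask)) {
    cell_thr <- .threshold_fun(cell_method)(frame)
    cell_mask <- frame > cell_thr
    cell_mask <- EBImage::closing(cell_mask * 1, EBImage::makeBrush(5, "disc")) > 0
    cell_mask <- EBImage::fillHull(cell_mask * 1) > 0
  } else {
    stopifnot(identical(dim(cell_mask), dim(frame)))
    cell_mask <- cell_mask > 0
  }
  empty_cell <- !any(cell_mask)
  if (empty_cell) warning("empty cell mask: no pixels above cell threshold")

  if (is.null(condensate_threshold)) {
    condensate_threshold <- .threshold_fun(condensate_method)(frame)
  }
  cond <- (frame > condensate_threshold) & cell_mask
  cond <- .remove_small_objects(cond, as.integer(min_object_px))

  structure(
    list(condensate_mask = cond, cell_mask = cell_mask,
         threshold_value = condensate_threshold, cell_threshold = cell_thr,
         method = condensate_method, min_object_px = as.integer(min_object_px),
         empty_cell = empty_cell),
    class = "segmentation"
  )
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "segmentation: %s threshold = %.6g; condensate %d px, cell %d px\n",
    x$method, x$threshold_value, sum(x$condensate_mask), sum(x$cell_mask)))
  invisible(x)
}

#' Segment every frame of a timelapse
#'
#' By default the condensate threshold is computed once on
#' `reference_frame` (the pre-treatment image) and held fixed for the whole
#' movie: re-thresholding each frame of a dissolving movie would hallucinate
#' foreground after dissolution. Set `reference_frame = NULL` to
#' re-threshold per frame. The cell mask is always taken from the reference
#' frame (or frame 1 when per-frame thresholding is requested).
#'
#' @param stack an [image_stack] (single plane per frame).
#' @param reference_frame index of the frame whose condensate threshold is
#'   held fixed, or `NULL` for per-frame thresholds. Default 1.
#' @inheritParams make_masks
#' @return List of `segmentation` objects, one per frame.
#' @export
segment_stack <- function(stack, condensate_method = "otsu",
                          cell_method = "mean", min_object_px = 4L,
                          reference_frame = 1L, cell_mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  ref_idx <- if (is.null(reference_frame)) 1L else as.integer(reference_frame)
  ref <- make_masks(get_frame(stack, ref_idx), condensate_method, cell_method,
                    min_object_px, cell_mask = cell_mask)
  thr <- if (is.null(reference_frame)) NULL else ref$threshold_value
  lapply(seq_len(stack$n_frames), function(i) {
    if (i == ref_idx) return(ref)
    make_masks(get_frame(stack, i), condensate_method, cell_method,
               min_object_px, condensate_threshold = thr,
               cell_mask = ref$cell_mask)
  })
}

#' Jaccard overlap between two masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return `|a & b| / |a | b|`; 1 when both masks are empty.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}
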