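#' Timelapse image stack
#'
#' Container for a fluorescence timelapse. Pixels are stored as a numeric
#' array in R's native column-major layout, `[y, x, frame]` for single-plane
#' stacks and `[y, x, z, frame]` when Z planes are retained pre-projection.
#' Intensities are in arbitrary camera units and must be finite and
#' non-negative.
#'
#' @param pixels numeric array, `[y, x, frame]` or `[y, x, z, frame]`.
#' @param times_s numeric vector of per-frame acquisition times in seconds,
#'   strictly increasing, one entry per frame.
#' @param channel_role one of `"scaffold"` (the condensate-forming protein),
#'   `"disruptor"` (the ligand recruited to trigger disassembly) or
#'   `"marker"`.
#' @return An object of class `image_stack` with elements `pixels`,
#'   `times_s`, `channel_role` and `n_frames`.
#' @export
image_stack <- function(pixels, times_s, channel_role = "scaffold") {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  nd <- length(dim(pixels))
  if (!nd %in% c(3L, 4L)) {
    stop("pixels must be a [y, x, frame] or [y, x, z, frame] array")
  }
  n_frames <- dim(pixels)[nd]
  if (length(times_s) != n_frames) {
    stop("times_s length (", length(times_s), ") != frame count (", n_frames, ")")
  }
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and >= 0")
  }
  channel_role <- match.arg(channel_role, c("scaffold", "disruptor", "marker"))
  structure(
    list(pixels = pixels, times_s = as.numeric(times_s),
         channel_role = channel_role, n_frames = n_frames),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  ztxt <- if (length(d) == 4L) paste0(", ", d[3], " Z planes") else ""
  cat(sprintf("image_stack: %d frame(s), %d x %d px%s, role=%s\n",
              x$n_frames, d[1], d[2], ztxt, x$channel_role))
  cat(sprintf("  t = %g .. %g s; intensity range [%g, %g]\n",
              x$times_s[1], x$times_s[x$n_frames],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Extract one frame as a matrix
#'
#' @param stack an [image_stack] (single-plane).
#' @param i frame index (1-based).
#' @return numeric matrix `[y, x]`.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(dim(stack$pixels)) != 3L) {
    stop("stack has Z planes; call max_project() first")
  }
  if (i < 1L || i > stack$n_frames) stop("frame index out of range")
  stack$pixels[, , i]
}

#' Maximal Z-projection
#'
#' Collapses the Z dimension of a confocal stack by taking the per-pixel
#' maximum across planes, the standard first step before thresholding.
#' Single-plane input is returned unchanged.
#'
#' @param stack an [image_stack], with or without a Z dimension.
#' @return An [image_stack] with pixels `[y, x, frame]`.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  if (length(d) == 3L) return(stack)
  proj <- apply(stack$pixels, c(1L, 2L, 4L), max)
  image_stack(proj, stack$times_s, stack$channel_role)
}
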