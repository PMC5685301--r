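#' Maximum-intensity Z projection
#'
#' Collapses a window of optical slices to a single 2D image by taking the
#' per-pixel maximum, the standard reduction used before colocalization and
#' particle analysis of confocal stacks.
#'
#' @param stack an [image_stack()].
#' @param slice_range integer vector of slice indices to project (1-based,
#'   inclusive); e.g. `1:10` projects the first ten optical slices. Defaults
#'   to all slices.
#' @return An object of class `nmj_projection`: a list with `pixels` (2D
#'   intensity matrix), `domain` (logical matrix of pixels included in the
#'   analysis; all `TRUE` here, restricted later by [crop_roi()]),
#'   the inherited calibration fields, and `source_slices`.
#' @seealso [crop_roi()], [apply_threshold_mask()]
#' @export
max_z_projection <- function(stack, slice_range = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nslice <- dim(stack$voxels)[3]
  if (is.null(slice_range)) slice_range <- seq_len(nslice)
  slice_range <- as.integer(slice_range)
  if (length(slice_range) == 0L)
    stop("`slice_range` must select at least one slice")
  if (anyNA(slice_range) || any(slice_range < 1L) || any(slice_range > nslice))
    stop(sprintf("`slice_range` out of range: stack has %d slice(s)", nslice))
  sub <- stack$voxels[, , slice_range, drop = FALSE]
  px <- apply(sub, c(1, 2), max)
  structure(
    list(pixels = px,
         domain = matrix(TRUE, nrow(px), ncol(px)),
         bit_depth = stack$bit_depth,
         pixel_size_xy = stack$pixel_size_xy,
         z_step = stack$z_step,
         channel = stack$channel,
         source_slices = range(slice_range)),
    class = "nmj_projection")
}

#' @export
print.nmj_projection <- function(x, ...) {
  cat(sprintf(
    "<nmj_projection> %s: %d x %d px (%d in analysis domain), slices %d-%d\n",
    if (nzchar(x$channel)) x$channel else "(unlabelled)",
    nrow(x$pixels), ncol(x$pixels), sum(x$domain),
    x$source_slices[1], x$source_slices[2]))
  invisible(x)
}

#' Rectangular region of interest
#'
#' Pixel bounds are 1-based and inclusive. `mode = "retain"` keeps only the
#' rectangle in the analysis domain; `mode = "exclude"` removes it (the
#' operation used to crop the myoseptum out of lateral-muscle fields).
#'
#' @param row_start,row_end,col_start,col_end integer pixel bounds,
#'   1-based inclusive.
#' @param mode `"retain"` or `"exclude"`.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(row_start, row_end, col_start, col_end,
                     mode = c("retain", "exclude")) {
  mode <- match.arg(mode)
  b <- vapply(list(row_start, row_end, col_start, col_end), as.integer,
              integer(1))
  if (anyNA(b) || b[1] > b[2] || b[3] > b[4] || any(b < 1L))
    stop("ROI bounds must satisfy 1 <= start <= end")
  structure(list(row_start = b[1], row_end = b[2],
                 col_start = b[3], col_end = b[4], mode = mode),
            class = "rect_roi")
}

#' Restrict a projection's analysis domain to or away from a rectangle
#'
#' Cropped-out pixels are removed from the analysis domain rather than set
#' to zero, so that percent-positive metrics and colocalization statistics
#' use the cropped denominator and are not biased by artificial zeros.
#'
#' @param image an `nmj_projection`.
#' @param roi a [rect_roi()].
#' @return The projection with an updated `domain`.
#' @export
crop_roi <- function(image, roi) {
  stopifnot(inherits(image, "nmj_projection"), inherits(roi, "rect_roi"))
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (roi$row_end > nr || roi$col_end > nc)
    stop(sprintf("ROI exceeds image bounds (%d x %d)", nr, nc))
  inside <- matrix(FALSE, nr, nc)
  inside[roi$row_start:roi$row_end, roi$col_start:roi$col_end] <- TRUE
  image$domain <- image$domain & (if (roi$mode == "retain") inside else !inside)
  if (!any(image$domain))
    stop("ROI cropping left an empty analysis domain")
  image
}

#' Mask a projection at a fixed intensity threshold
#'
#' Keeps original intensities strictly above the threshold and zeroes the
#' rest, mirroring the mask-and-image-calculator filtering step applied to
#' each channel before colocalization. The analysis domain is unchanged.
#'
#' @param image an `nmj_projection`.
#' @param threshold integer threshold on the native intensity scale; pixels
#'   with intensity `> threshold` pass.
#' @return A list with `mask` (class `binary_mask`: logical `pixels`,
#'   `domain`, `threshold_used`, calibration) and `masked` (the thresholded
#'   `nmj_projection`).
#' @export
apply_threshold_mask <- function(image, threshold) {
  stopifnot(inherits(image, "nmj_projection"))
  threshold <- as.numeric(threshold)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 ||
      threshold > 2^image$bit_depth - 1)
    stop("`threshold` must be a single value within the bit-depth range")
  mask_px <- image$pixels > threshold
  masked <- image
  masked$pixels <- ifelse(mask_px, image$pixels, 0L)
  mask <- structure(
    list(pixels = mask_px, domain = image$domain,
         threshold_used = threshold,
         pixel_size_xy = image$pixel_size_xy,
         channel = image$channel),
    class = "binary_mask")
  list(mask = mask, masked = masked)
}
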