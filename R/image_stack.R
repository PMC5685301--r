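#' Single-channel confocal image stack
#'
#' Container for one fluorescence channel of a confocal acquisition: a 3D
#' grid of non-negative integer intensities with its pixel calibration.
#' Voxels are stored as an R array with `dim = c(rows, cols, slices)`, so
#' `voxels[, , k]` is optical slice `k` (slice order = TIFF page order).
#'
#' @param voxels numeric array of dimension `c(rows, cols, slices)` (a matrix
#'   is promoted to a single-slice stack); values must be non-negative
#'   integers within the bit depth.
#' @param bit_depth 8 or 16.
#' @param pixel_size_xy lateral calibration, micrometres per pixel.
#' @param z_step axial calibration, micrometres per optical slice.
#' @param channel free-text channel label, e.g. `"SYT2"` or `"AChR"`.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, bit_depth = 8, pixel_size_xy = 1,
                        z_step = 1, channel = "") {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a rows x cols x slices array")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (pixel_size_xy <= 0 || z_step <= 0)
    stop("calibration values must be positive")
  v <- as.numeric(voxels)
  if (anyNA(v) || any(v < 0) || any(v > 2^bit_depth - 1) ||
      any(v != floor(v)))
    stop("intensities must be integers in [0, 2^bit_depth - 1]")
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels, bit_depth = as.integer(bit_depth),
         pixel_size_xy = pixel_size_xy, z_step = z_step,
         channel = channel),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %s: %d x %d px, %d slice(s), %d-bit, %.3g um/px, %.3g um z-step\n",
    if (nzchar(x$channel)) x$channel else "(unlabelled)",
    d[1], d[2], d[3], x$bit_depth, x$pixel_size_xy, x$z_step))
  invisible(x)
}

#' Aligned red/green channel pair
#'
#' Binds the presynaptic (red, e.g. SYT2) and postsynaptic (green, e.g.
#' alpha-bungarotoxin-labelled AChR) channels of one larva into the unit of
#' imaging analysis. Shapes and calibration must match.
#'
#' @param red,green `image_stack` objects of identical shape and calibration.
#' @return An object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(red, green) {
  stopifnot(inherits(red, "image_stack"), inherits(green, "image_stack"))
  if (!identical(dim(red$voxels), dim(green$voxels)))
    stop("red and green stacks must have identical shape")
  if (red$pixel_size_xy != green$pixel_size_xy || red$z_step != green$z_step ||
      red$bit_depth != green$bit_depth)
    stop("red and green stacks must share calibration and bit depth")
  structure(list(red = red, green = green), class = "two_channel_stack")
}

#' @export
print.two_channel_stack <- function(x, ...) {
  cat("<two_channel_stack>\n  red:   ")
  print(x$red)
  cat("  green: ")
  print(x$green)
  invisible(x)
}
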