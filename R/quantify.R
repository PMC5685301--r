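#' Full per-larva NMJ quantification
#'
#' Runs the complete confocal quantification on one red/green stack pair:
#' maximum-intensity projection over the selected slices, per-channel Kapur
#' maximum-entropy thresholding, masking, optional ROI cropping (e.g. to
#' exclude the myoseptum), Manders and Pearson colocalization on the masked
#' channels, and per-channel particle analysis. Deterministic for fixed
#' input.
#'
#' @param pair a [two_channel_stack()].
#' @param slice_range slice indices to project (1-based, inclusive);
#'   default all slices.
#' @param roi optional [rect_roi()] applied to both channels after masking.
#' @param min_area_pixels particle size filter, see [analyze_particles()].
#' @param larva_id identifier copied into the output record.
#' @param thresholds optional fixed native-scale thresholds
#'   `c(red = , green = )` overriding the automatic Kapur step (the manual
#'   analogue of setting a threshold by hand in an image viewer); `NULL`
#'   (default) uses per-channel maximum-entropy thresholds.
#' @return An object of class `nmj_metrics`: a one-row data.frame with
#'   columns `larva_id`, `pct_red`, `pct_green`, `n_red_particles`,
#'   `n_green_particles`, `mean_green_particle_area_um2`, `M1`, `M2`,
#'   `pearson`, plus attribute `thresholds` (native-scale red/green
#'   thresholds used).
#' @export
quantify_nmj <- function(pair, slice_range = NULL, roi = NULL,
                         min_area_pixels = 0, larva_id = "larva",
                         thresholds = NULL) {
  stopifnot(inherits(pair, "two_channel_stack"))
  if (!is.null(thresholds) &&
      !all(c("red", "green") %in% names(thresholds)))
    stop("`thresholds` must be a named vector with elements 'red' and 'green'")
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  proj_r <- with_stage("projection/red",
                       max_z_projection(pair$red, slice_range))
  proj_g <- with_stage("projection/green",
                       max_z_projection(pair$green, slice_range))
  thr_r <- if (is.null(thresholds))
    with_stage("threshold/red", kapur_threshold_image(proj_r))
  else unname(thresholds["red"])
  thr_g <- if (is.null(thresholds))
    with_stage("threshold/green", kapur_threshold_image(proj_g))
  else unname(thresholds["green"])
  mr <- with_stage("mask/red", apply_threshold_mask(proj_r, thr_r))
  mg <- with_stage("mask/green", apply_threshold_mask(proj_g, thr_g))
  if (!is.null(roi)) {
    mr$masked <- with_stage("crop/red", crop_roi(mr$masked, roi))
    mg$masked <- with_stage("crop/green", crop_roi(mg$masked, roi))
    mr$mask$domain <- mr$masked$domain
    mg$mask$domain <- mg$masked$domain
  }
  mm <- with_stage("manders", manders_coefficients(mr$masked, mg$masked))
  pear <- with_stage("pearson", tryCatch(
    pearson_coefficient(mr$masked, mg$masked),
    warning = function(w) { warning(w); NA_real_ }))
  part_r <- with_stage("particles/red",
                       analyze_particles(mr$mask, min_area_pixels))
  part_g <- with_stage("particles/green",
                       analyze_particles(mg$mask, min_area_pixels))
  out <- data.frame(
    larva_id = larva_id,
    pct_red = part_r$percent_positive_pixels,
    pct_green = part_g$percent_positive_pixels,
    n_red_particles = part_r$n_particles,
    n_green_particles = part_g$n_particles,
    mean_green_particle_area_um2 =
      if (part_g$n_particles > 0) mean(part_g$particles$area_um2) else NA_real_,
    M1 = mm$M1, M2 = mm$M2, pearson = pear,
    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(red = thr_r, green = thr_g)
  class(out) <- c("nmj_metrics", "data.frame")
  out
}

#' @export
print.nmj_metrics <- function(x, digits = 3, ...) {
  cat("<nmj_metrics>\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  thr <- attr(x, "thresholds")
  if (!is.null(thr))
    cat(sprintf("thresholds: red > %g, green > %g\n", thr["red"], thr["green"]))
  invisible(x)
}
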