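#' Manders colocalization coefficients
#'
#' M1 is the fraction of total red intensity falling on pixels where the
#' green channel is positive; M2 the converse. Inputs are expected to be
#' already thresholded/masked projections (the auto-threshold step is done
#' upstream), so positivity means intensity strictly greater than zero.
#' Only pixels in the shared analysis domain contribute.
#'
#' A channel that is entirely zero within the domain makes its coefficient
#' undefined: the value is returned as `NA` with a warning, never silently
#' as 0.
#'
#' @param red_masked,green_masked `nmj_projection` objects of identical
#'   shape (typically the `masked` element of [apply_threshold_mask()]).
#' @return A list with elements `M1` and `M2`, each in \[0, 1\] or `NA`.
#' @export
manders_coefficients <- function(red_masked, green_masked) {
  px <- coloc_pixel_pairs(red_masked, green_masked)
  r <- px$r; g <- px$g
  M1 <- if (sum(r) > 0) sum(r[g > 0]) / sum(r) else {
    warning("red channel empty within domain: M1 undefined, returned NA")
    NA_real_
  }
  M2 <- if (sum(g) > 0) sum(g[r > 0]) / sum(g) else {
    warning("green channel empty within domain: M2 undefined, returned NA")
    NA_real_
  }
  list(M1 = M1, M2 = M2)
}

#' Pearson correlation between two masked channels
#'
#' Product-moment correlation of the per-pixel intensity pairs over the
#' shared analysis domain. Zero variance in either channel makes the
#' coefficient undefined (`NA` with a warning).
#'
#' @inheritParams manders_coefficients
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_coefficient <- function(red_masked, green_masked) {
  px <- coloc_pixel_pairs(red_masked, green_masked)
  if (length(px$r) < 2L)
    stop("Pearson correlation needs at least two in-domain pixels")
  if (sd(px$r) == 0 || sd(px$g) == 0) {
    warning("zero variance in a channel: Pearson coefficient undefined, returned NA")
    return(NA_real_)
  }
  cor(px$r, px$g)
}

# shared validation: align two projections and extract in-domain pixel pairs
coloc_pixel_pairs <- function(red_masked, green_masked) {
  stopifnot(inherits(red_masked, "nmj_projection"),
            inherits(green_masked, "nmj_projection"))
  if (!identical(dim(red_masked$pixels), dim(green_masked$pixels)))
    stop("channel projections must have identical shape")
  dom <- red_masked$domain & green_masked$domain
  if (!any(dom)) stop("empty shared analysis domain")
  list(r = as.numeric(red_masked$pixels[dom]),
       g = as.numeric(green_masked$pixels[dom]))
}
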