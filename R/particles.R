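#' Particle analysis of a binary mask
#'
#' Labels 8-connected components of the thresholded mask within the
#' analysis domain and reports per-particle pixel and calibrated areas,
#' centroids, and the percent of in-domain pixels above threshold. Because
#' it operates on the binary mask, the result is insensitive to staining
#' intensity.
#'
#' @param mask a `binary_mask` (from [apply_threshold_mask()]).
#' @param min_area_pixels drop particles smaller than this many pixels
#'   (default 0: no size filter). `percent_positive_pixels` always counts
#'   all above-threshold in-domain pixels, independent of the filter.
#' @return An object of class `particle_set`: list with `particles`
#'   (data.frame: `label`, `area_pixels`, `area_um2`, `centroid_row`,
#'   `centroid_col`), `percent_positive_pixels`, `n_particles`,
#'   `domain_pixels`.
#' @export
analyze_particles <- function(mask, min_area_pixels = 0) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$domain)) stop("empty analysis domain")
  fg <- mask$pixels & mask$domain
  lab <- label_components_8(fg)
  n_pos <- sum(fg)
  pct <- 100 * n_pos / sum(mask$domain)
  if (max(lab) == 0L) {
    particles <- data.frame(label = integer(), area_pixels = integer(),
                            area_um2 = numeric(), centroid_row = numeric(),
                            centroid_col = numeric())
  } else {
    idx <- which(lab > 0L)
    rc <- arrayInd(idx, dim(lab))
    lv <- lab[idx]
    area <- as.integer(tabulate(lv))
    particles <- data.frame(
      label = seq_along(area),
      area_pixels = area,
      area_um2 = area * mask$pixel_size_xy^2,
      centroid_row = as.numeric(tapply(rc[, 1], lv, mean)),
      centroid_col = as.numeric(tapply(rc[, 2], lv, mean)))
    particles <- particles[particles$area_pixels >= min_area_pixels, ,
                           drop = FALSE]
    rownames(particles) <- NULL
  }
  structure(
    list(particles = particles,
         percent_positive_pixels = pct,
         n_particles = nrow(particles),
         domain_pixels = sum(mask$domain)),
    class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particle(s), %.2f%% positive pixels (domain %d px)\n",
              x$n_particles, x$percent_positive_pixels, x$domain_pixels))
  invisible(x)
}

# 8-connected component labelling by frontier flood fill.
# fg: logical matrix. Returns an integer matrix of labels (0 = background).
label_components_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  seeds <- which(fg)
  if (length(seeds) == 0L) return(lab)
  # linear-index offsets of the 8 neighbours; border safety via row checks
  cur <- 0L
  for (p in seeds) {
    if (lab[p] > 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    frontier <- p
    while (length(frontier) > 0L) {
      r <- (frontier - 1L) %% nr + 1L
      cl <- (frontier - 1L) %/% nr + 1L
      nbr_r <- rep(r, times = 8L) + rep(c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                                        each = length(frontier))
      nbr_c <- rep(cl, times = 8L) + rep(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                                         each = length(frontier))
      ok <- nbr_r >= 1L & nbr_r <= nr & nbr_c >= 1L & nbr_c <= nc
      nidx <- unique((nbr_c[ok] - 1L) * nr + nbr_r[ok])
      nidx <- nidx[fg[nidx] & lab[nidx] == 0L]
      lab[nidx] <- cur
      frontier <- nidx
    }
  }
  lab
}

#' Polyline length in calibrated units
#'
#' Sums Euclidean segment lengths of a traced path (e.g. a motor axon
#' traced from a projection) and converts to micrometres.
#'
#' @param vertices numeric matrix with 2 columns (row, col) of at least two
#'   traced points, in pixel coordinates.
#' @param pixel_size_xy micrometres per pixel.
#' @return Length in micrometres.
#' @export
measure_axon_length <- function(vertices, pixel_size_xy) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    stop("`vertices` must be a matrix of >= 2 (row, col) points")
  if (pixel_size_xy <= 0) stop("`pixel_size_xy` must be positive")
  d <- diff(vertices)
  sum(sqrt(rowSums(d^2))) * pixel_size_xy
}
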