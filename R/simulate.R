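#' Parameters for the synthetic NMJ stack generator
#'
#' Defaults emulate the acquisition regime of the assay: ten ~1-um optical
#' slices into the lateral muscle, punctate presynaptic staining (small
#' SYT2-like red puncta at axon tips) over larger postsynaptic AChR-like
#' green clusters, with a controllable fraction of red puncta truly sitting
#' inside green clusters.
#'
#' @param shape integer vector `c(rows, cols, slices)` in pixels/slices.
#' @param n_red_puncta,n_green_clusters object counts per stack.
#' @param coloc_fraction fraction of red puncta placed inside green
#'   clusters (the ground-truth colocalization knob), in \[0, 1\].
#' @param punctum_radius_um,cluster_radius_um Gaussian radius (sigma) of
#'   red puncta and green clusters, micrometres.
#' @param peak_red,peak_green peak object intensities (native units).
#' @param psf_sigma_um lateral PSF sigma, micrometres; axial sigma is
#'   `psf_axial_factor` times larger, as typical for confocal optics.
#' @param psf_axial_factor axial/lateral PSF sigma ratio (default 3).
#' @param background constant background offset added after the shot-noise
#'   step.
#' @param gaussian_sd additive Gaussian read-noise SD.
#' @param poisson_noise apply Poisson shot noise to the object signal.
#' @param pixel_size_xy,z_step calibration, micrometres.
#' @param bit_depth 8 or 16.
#' @param min_separation_um non-colocalized red puncta are rejected closer
#'   than this to any green cluster centre; default
#'   `2 * (cluster_radius_um + punctum_radius_um)` keeps them clear of
#'   green-positive pixels.
#' @param cluster_min_spacing_um minimum lateral distance between green
#'   cluster centres (rejection-sampled). Default 0: clusters may touch or
#'   merge, as real AChR clusters do; set to roughly 4 sigma to obtain
#'   well-separated clusters for counting constructions.
#' @return A list of class `synthetic_nmj_params`.
#' @export
synthetic_nmj_params <- function(shape = c(128L, 128L, 10L),
                                 n_red_puncta = 60,
                                 n_green_clusters = 20,
                                 coloc_fraction = 0.5,
                                 punctum_radius_um = 0.3,
                                 cluster_radius_um = 1.0,
                                 peak_red = 140,
                                 peak_green = 160,
                                 psf_sigma_um = 0.15,
                                 psf_axial_factor = 3,
                                 background = 8,
                                 gaussian_sd = 2,
                                 poisson_noise = TRUE,
                                 pixel_size_xy = 0.2,
                                 z_step = 1.0,
                                 bit_depth = 8,
                                 min_separation_um = NULL,
                                 cluster_min_spacing_um = 0) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("`coloc_fraction` must be in [0, 1]")
  if (punctum_radius_um <= 0 || cluster_radius_um <= 0 || psf_sigma_um <= 0)
    stop("radii and PSF sigma must be positive")
  if (is.null(min_separation_um))
    min_separation_um <- 1.5 * (cluster_radius_um + punctum_radius_um)
  p <- list(shape = as.integer(shape), n_red_puncta = as.integer(n_red_puncta),
            n_green_clusters = as.integer(n_green_clusters),
            coloc_fraction = coloc_fraction,
            punctum_radius_um = punctum_radius_um,
            cluster_radius_um = cluster_radius_um,
            peak_red = peak_red, peak_green = peak_green,
            psf_sigma_um = psf_sigma_um, psf_axial_factor = psf_axial_factor,
            background = background, gaussian_sd = gaussian_sd,
            poisson_noise = isTRUE(poisson_noise),
            pixel_size_xy = pixel_size_xy, z_step = z_step,
            bit_depth = as.integer(bit_depth),
            min_separation_um = min_separation_um,
            cluster_min_spacing_um = cluster_min_spacing_um)
  class(p) <- "synthetic_nmj_params"
  p
}

# Add Gaussian objects to a volume. centers: n x 3 matrix (row, col, slice)
# in continuous voxel coordinates. sigma_xy/sigma_z in voxel units.
render_gaussians <- function(vol, centers, peak, sigma_xy, sigma_z) {
  d <- dim(vol)
  hw_xy <- ceiling(4 * sigma_xy); hw_z <- ceiling(4 * sigma_z)
  for (i in seq_len(nrow(centers))) {
    cr <- centers[i, 1]; cc <- centers[i, 2]; cs <- centers[i, 3]
    rr <- max(1, floor(cr - hw_xy)):min(d[1], ceiling(cr + hw_xy))
    cc_ <- max(1, floor(cc - hw_xy)):min(d[2], ceiling(cc + hw_xy))
    ss <- max(1, floor(cs - hw_z)):min(d[3], ceiling(cs + hw_z))
    gr <- exp(-(rr - cr)^2 / (2 * sigma_xy^2))
    gc <- exp(-(cc_ - cc)^2 / (2 * sigma_xy^2))
    gs <- exp(-(ss - cs)^2 / (2 * sigma_z^2))
    blob <- peak * outer(outer(gr, gc), gs)
    vol[rr, cc_, ss] <- vol[rr, cc_, ss] + blob
  }
  vol
}

#' Generate a ground-truthed synthetic two-channel NMJ stack
#'
#' Green AChR-like clusters are placed uniformly at random (respecting a
#' border margin); `round(coloc_fraction * n_red_puncta)` red puncta are
#' centred inside randomly chosen green clusters with jitter up to half the
#' cluster radius, and the remainder are placed uniformly away from green
#' clusters. Objects are Gaussian blobs; blurring by the Gaussian PSF is
#' applied analytically (object sigma and PSF sigma add in quadrature,
#' which is exact for Gaussian objects). Poisson shot noise is applied to
#' the object signal, then the constant background is added, then Gaussian
#' read noise; intensities are rounded and clipped to the bit depth.
#' Deterministic for a fixed seed.
#'
#' @param params a [synthetic_nmj_params()] list.
#' @param seed integer RNG seed.
#' @return A list with `stack` (a [two_channel_stack()]) and `truth`
#'   (ground truth: object counts, `coloc_fraction`, `n_coloc_red`, seed).
#' @export
generate_nmj_stack <- function(params = synthetic_nmj_params(), seed = 1) {
  stopifnot(inherits(params, "synthetic_nmj_params"))
  set.seed(seed)
  d <- params$shape
  px <- params$pixel_size_xy; zs <- params$z_step
  sig_g_xy <- sqrt(params$cluster_radius_um^2 + params$psf_sigma_um^2) / px
  sig_g_z <- sqrt(params$cluster_radius_um^2 +
                    (params$psf_axial_factor * params$psf_sigma_um)^2) / zs
  sig_r_xy <- sqrt(params$punctum_radius_um^2 + params$psf_sigma_um^2) / px
  sig_r_z <- sqrt(params$punctum_radius_um^2 +
                    (params$psf_axial_factor * params$psf_sigma_um)^2) / zs
  # each object type keeps its own footprint inside the volume
  margin_g <- ceiling(3 * sig_g_xy) + 1
  margin_r <- ceiling(3 * sig_r_xy) + 1
  if (2 * margin_g >= min(d[1], d[2]))
    stop("objects cannot fit: volume too small for the cluster radius")
  runif_centers <- function(n, margin = margin_g) {
    cbind(runif(n, margin, d[1] - margin),
          runif(n, margin, d[2] - margin),
          runif(n, 1.5, d[3] - 0.5))
  }
  g_centers <- if (params$cluster_min_spacing_um > 0) {
    spac_px <- params$cluster_min_spacing_um / px
    acc <- matrix(numeric(0), 0, 3)
    tries <- 0L
    while (nrow(acc) < params$n_green_clusters) {
      tries <- tries + 1L
      if (tries > 500L * params$n_green_clusters)
        stop("objects cannot fit: cluster spacing too large for the volume")
      cand <- runif_centers(1L)
      if (nrow(acc) == 0L ||
          min(sqrt((acc[, 1] - cand[1])^2 + (acc[, 2] - cand[2])^2)) >
            spac_px)
        acc <- rbind(acc, cand)
    }
    acc
  } else runif_centers(params$n_green_clusters)
  n_coloc <- round(params$coloc_fraction * params$n_red_puncta)
  n_free <- params$n_red_puncta - n_coloc
  r_centers <- matrix(numeric(0), 0, 3)
  if (n_coloc > 0) {
    host <- sample.int(params$n_green_clusters, n_coloc, replace = TRUE)
    jit_r <- params$cluster_radius_um / 2 / px
    jit_z <- params$cluster_radius_um / 2 / zs
    r_centers <- g_centers[host, , drop = FALSE] +
      cbind(runif(n_coloc, -jit_r, jit_r), runif(n_coloc, -jit_r, jit_r),
            runif(n_coloc, -jit_z, jit_z))
    r_centers[, 3] <- pmin(pmax(r_centers[, 3], 1), d[3])
  }
  if (n_free > 0) {
    sep_px <- params$min_separation_um / px
    free <- matrix(NA_real_, n_free, 3)
    placed <- 0L; tries <- 0L
    while (placed < n_free) {
      tries <- tries + 1L
      if (tries > 200L * n_free)
        stop("objects cannot fit: could not place non-colocalized puncta ",
             "away from green clusters")
      cand <- runif_centers(1L, margin_r)
      dist_xy <- sqrt((g_centers[, 1] - cand[1])^2 +
                        (g_centers[, 2] - cand[2])^2)
      if (min(dist_xy) > sep_px) {
        placed <- placed + 1L
        free[placed, ] <- cand
      }
    }
    r_centers <- rbind(r_centers, free)
  }
  green <- render_gaussians(array(0, d), g_centers, params$peak_green,
                            sig_g_xy, sig_g_z)
  red <- render_gaussians(array(0, d), r_centers, params$peak_red,
                          sig_r_xy, sig_r_z)
  finish <- function(sig) {
    if (params$poisson_noise) sig <- array(rpois(length(sig), sig), d)
    sig <- sig + params$background
    if (params$gaussian_sd > 0)
      sig <- sig + array(rnorm(length(sig), 0, params$gaussian_sd), d)
    array(pmin(pmax(round(sig), 0), 2^params$bit_depth - 1), d)
  }
  stack <- two_channel_stack(
    image_stack(finish(red), params$bit_depth, px, zs, "SYT2"),
    image_stack(finish(green), params$bit_depth, px, zs, "AChR"))
  truth <- list(n_red_puncta = params$n_red_puncta,
                n_green_clusters = params$n_green_clusters,
                coloc_fraction = params$coloc_fraction,
                n_coloc_red = n_coloc, seed = seed)
  list(stack = stack, truth = truth)
}

#' Parameters for the synthetic plate-assay trajectory generator
#'
#' Defaults emulate the visual stimulus assay: 50 larvae per trough, a
#' 15-minute (900 s) white-background baseline followed by a 600 s
#' moving-bar stimulus under the upper half, sampled at 1 frame/s.
#'
#' @param n_larvae larvae per trough.
#' @param duration_s total recording length, seconds.
#' @param frame_interval_s seconds between frames.
#' @param trough_length_mm,trough_width_mm trough dimensions.
#' @param baseline_speed_mm_s nominal swim speed.
#' @param heading_noise_sd per-frame heading perturbation SD, radians.
#' @param p_avoid per-frame probability (during the stimulus) that a larva
#'   reorients toward the unstimulated half.
#' @param stimulus_start_s,stimulus_end_s stimulus window.
#' @param stimulated_half `"upper"` or `"lower"`.
#' @return A list of class `synthetic_behavior_params`.
#' @export
synthetic_behavior_params <- function(n_larvae = 50,
                                      duration_s = 1500,
                                      frame_interval_s = 1,
                                      trough_length_mm = 50,
                                      trough_width_mm = 10,
                                      baseline_speed_mm_s = 1.5,
                                      heading_noise_sd = 0.3,
                                      p_avoid = 0.1,
                                      stimulus_start_s = 900,
                                      stimulus_end_s = 1500,
                                      stimulated_half = "upper") {
  if (p_avoid < 0 || p_avoid > 1) stop("`p_avoid` must be in [0, 1]")
  if (baseline_speed_mm_s < 0) stop("speed must be non-negative")
  p <- list(n_larvae = as.integer(n_larvae), duration_s = duration_s,
            frame_interval_s = frame_interval_s,
            trough_length_mm = trough_length_mm,
            trough_width_mm = trough_width_mm,
            baseline_speed_mm_s = baseline_speed_mm_s,
            heading_noise_sd = heading_noise_sd, p_avoid = p_avoid,
            stimulus_start_s = stimulus_start_s,
            stimulus_end_s = stimulus_end_s,
            stimulated_half = match.arg(stimulated_half, c("upper", "lower")))
  class(p) <- "synthetic_behavior_params"
  p
}

#' Generate ground-truthed plate-assay trajectories
#'
#' Each larva performs a reflected random walk at the nominal speed with
#' Gaussian heading noise. During the stimulus window, a larva currently in
#' the stimulated half (i.e. over the moving bar) is redirected toward the
#' unstimulated half with probability `p_avoid` per frame, before the noise
#' perturbation; larvae already in the unstimulated half swim undisturbed,
#' so occupancy equilibrates rather than absorbing. Positions are rounded
#' to 1 um (the working resolution of centroid tracking), and the walk is
#' deterministic for a fixed seed.
#'
#' @param params a [synthetic_behavior_params()] list.
#' @param seed integer RNG seed.
#' @return A list with `tracks` (a [trajectory_set()]) and `truth`
#'   (`p_avoid`, `baseline_speed_mm_s`, `n_larvae`, seed).
#' @export
generate_behavior <- function(params = synthetic_behavior_params(), seed = 1) {
  stopifnot(inherits(params, "synthetic_behavior_params"))
  set.seed(seed)
  L <- params$trough_length_mm; W <- params$trough_width_mm
  step <- params$baseline_speed_mm_s * params$frame_interval_s
  if (step > min(L, W) / 2)
    stop("trough too small for the per-frame step size")
  n <- params$n_larvae
  n_frames <- floor(params$duration_s / params$frame_interval_s) + 1L
  times <- (seq_len(n_frames) - 1L) * params$frame_interval_s
  x <- runif(n, 0, W); y <- runif(n, 0, L)
  heading <- runif(n, -pi, pi)
  # heading pointing toward the unstimulated half along the trough axis
  avoid_heading <- if (params$stimulated_half == "upper") -pi / 2 else pi / 2
  X <- matrix(NA_real_, n_frames, n); Y <- matrix(NA_real_, n_frames, n)
  X[1, ] <- x; Y[1, ] <- y
  # fold a coordinate back into [0, lim]; report which larvae bounced so
  # the heading component can be mirrored too (billiard reflection)
  reflect <- function(v, lim) {
    hit <- v < 0 | v > lim
    v <- abs(v)
    over <- v > lim
    v[over] <- 2 * lim - v[over]
    list(v = pmin(pmax(v, 0), lim), hit = hit)
  }
  for (f in 2L:n_frames) {
    t_now <- times[f]
    in_stim <- t_now >= params$stimulus_start_s &&
      t_now <= params$stimulus_end_s
    if (in_stim && params$p_avoid > 0) {
      # only larvae currently over the bar (stimulated half) respond
      exposed <- if (params$stimulated_half == "upper")
        y > L / 2 else y < L / 2
      redirect <- exposed & runif(n) < params$p_avoid
      heading[redirect] <- avoid_heading
    }
    heading <- heading + rnorm(n, 0, params$heading_noise_sd)
    rx <- reflect(x + step * cos(heading), W)
    ry <- reflect(y + step * sin(heading), L)
    x <- rx$v; y <- ry$v
    heading[rx$hit] <- pi - heading[rx$hit]   # mirror x-component
    heading[ry$hit] <- -heading[ry$hit]       # mirror y-component
    X[f, ] <- x; Y[f, ] <- y
  }
  tracks <- data.frame(
    larva_id = rep(sprintf("larva_%02d", seq_len(n)), each = n_frames),
    frame = rep(seq_len(n_frames), n),
    time_s = rep(times, n),
    x_mm = round(as.numeric(X), 3),
    y_mm = round(as.numeric(Y), 3))
  ts <- trajectory_set(tracks, L, W,
                       params$stimulus_start_s, params$stimulus_end_s,
                       params$stimulated_half, params$frame_interval_s)
  truth <- list(p_avoid = params$p_avoid,
                baseline_speed_mm_s = params$baseline_speed_mm_s,
                n_larvae = n, seed = seed)
  list(tracks = ts, truth = truth)
}
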