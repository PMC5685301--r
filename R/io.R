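#' Read a multi-page grayscale TIFF as an image stack
#'
#' Pages become optical slices in file order. RGB/multi-sample TIFFs are
#' rejected with a format error; bit depth is detected from the file.
#'
#' @param path TIFF file path.
#' @param pixel_size_xy,z_step calibration to attach (micrometres).
#' @param channel channel label to attach.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_xy = 1, z_step = 1, channel = "") {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e)
      stop(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop(sprintf("'%s' is not single-channel grayscale (RGB or multi-sample pages found)",
                 path))
  bits <- attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  if (!bits %in% c(8L, 16L))
    stop(sprintf("'%s' has unsupported bit depth %d (need 8 or 16)", path, bits))
  vox <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    if (!identical(dim(pages[[k]]), dim(pages[[1]])))
      stop(sprintf("'%s': page %d shape differs from page 1", path, k))
    vox[, , k] <- pages[[k]]
  }
  image_stack(vox, bit_depth = as.integer(bits),
              pixel_size_xy = pixel_size_xy, z_step = z_step,
              channel = channel)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Lossless for integer intensities within the stack's bit depth:
#' write-then-read reproduces the voxels exactly.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxv <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(dim(stack$voxels)[3]),
                  function(k) stack$voxels[, , k] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none")
  invisible(path)
}

#' Read larval position tracks from CSV
#'
#' Requires columns `larva_id`, `frame`, `time_s`, `x_mm`, `y_mm`; any
#' additional columns are preserved as passthrough attributes. Geometry
#' and stimulus protocol come from the arguments (typically a run config).
#'
#' @param path CSV file path.
#' @inheritParams trajectory_set
#' @return A [trajectory_set()].
#' @export
read_tracks <- function(path, trough_length_mm, trough_width_mm,
                        stimulus_start_s, stimulus_end_s,
                        stimulated_half = "upper", frame_interval_s = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "frame", "time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("'%s' missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), need)
  ts <- trajectory_set(df, trough_length_mm, trough_width_mm,
                       stimulus_start_s, stimulus_end_s, stimulated_half,
                       frame_interval_s)
  if (length(extra) > 0)
    attr(ts, "passthrough") <- df[, extra, drop = FALSE]
  ts
}

#' Write a metrics table to CSV
#'
#' @param rows a data.frame (e.g. bound `nmj_metrics` rows or the output of
#'   [swim_speed()] / [summarize_groups()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(rows, path) {
  write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#' Defaults are filled for any missing field; see [default_run_config()].
#'
#' @param path config file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop(sprintf("unsupported config extension '.%s' (use YAML or JSON)", ext)))
  as_run_config(cfg)
}

#' Default run configuration
#'
#' @return A named list of class `run_config` with the package defaults:
#'   calibration, slice window, no ROI, plate geometry and stimulus
#'   protocol, stats options, and simulation group definitions used by
#'   [run_all()].
#' @export
default_run_config <- function() {
  as_run_config(list())
}

as_run_config <- function(cfg) {
  def <- list(
    pixel_size_xy = 0.2, z_step = 1.0, frame_interval_s = 1,
    slice_range = c(1, 10),
    roi = NULL,
    trough_length_mm = 50, trough_width_mm = 10,
    stimulus_start_s = 900, stimulus_end_s = 1500,
    stimulated_half = "upper",
    alpha = 0.05, tail = "two", outlier_rejection = TRUE,
    n_images_per_group = 10,
    groups = list(
      control = list(),
      treated = list(nmj = list(coloc_fraction = 0.25),
                     behavior = list(p_avoid = 0.02,
                                     baseline_speed_mm_s = 0.5))))
  for (nm in names(cfg)) def[[nm]] <- cfg[[nm]]
  if (def$pixel_size_xy <= 0 || def$z_step <= 0 || def$frame_interval_s <= 0)
    stop("calibration values must be positive")
  class(def) <- "run_config"
  def
}

#' Run the full synthetic-study pipeline
#'
#' For each configured group: simulates NMJ stacks and plate-assay tracks
#' (group entries may override any generator parameter), quantifies every
#' stack with [quantify_nmj()], computes [percent_down()] and
#' [swim_speed()], then compares groups with Thompson tau rejection and
#' pooled t-tests. Writes per-larva CSVs, group comparison CSVs and a JSON
#' manifest (config, seeds, output MD5 hashes) to `out_dir`. Every stage is
#' logged to `stderr`. Deterministic for fixed `seed`.
#'
#' @param config a `run_config` list (from [read_run_config()] /
#'   [default_run_config()]) or a path to a YAML/JSON config.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param quiet suppress progress logging.
#' @return A list of class `run_report`: `nmj_metrics` (data.frame),
#'   `nmj_comparison` (per-metric [compare_groups()] results),
#'   `behavior` (per-group percent_down and speed summary),
#'   `behavior_tests`, `manifest`.
#' @export
run_all <- function(config = default_run_config(), out_dir = tempfile("run_"),
                    seed = 1, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  # derived stage seeds, kept within 32-bit integer range
  derive_seed <- function(k)
    as.integer((as.numeric(seed) * 69069 + k) %% 2147483629)
  groups <- names(config$groups)
  roi <- if (!is.null(config$roi))
    do.call(rect_roi, config$roi)
  # imaging arm -----------------------------------------------------------
  nmj_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ov <- config$groups[[g]]$nmj
    par_args <- utils::modifyList(
      list(pixel_size_xy = config$pixel_size_xy, z_step = config$z_step),
      if (is.null(ov)) list() else ov)
    params <- do.call(synthetic_nmj_params, par_args)
    for (i in seq_len(config$n_images_per_group)) {
      sd_i <- derive_seed(gi * 1000L + i)
      log_msg("[simulate-nmj] group=%s image=%d seed=%d", g, i, sd_i)
      sim <- generate_nmj_stack(params, seed = sd_i)
      depth <- dim(sim$stack$red$voxels)[3]
      m <- quantify_nmj(sim$stack,
                        slice_range = seq(min(config$slice_range[1], depth),
                                          min(config$slice_range[2], depth)),
                        roi = roi,
                        larva_id = sprintf("%s_%02d", g, i))
      m$group <- g
      nmj_rows[[length(nmj_rows) + 1L]] <- m
    }
  }
  nmj <- do.call(rbind, lapply(nmj_rows, as.data.frame))
  nmj <- nmj[, c("larva_id", "group", setdiff(names(nmj),
                                              c("larva_id", "group")))]
  metric_cols <- c("pct_red", "pct_green", "M1", "M2", "pearson")
  nmj_cmp <- lapply(metric_cols, function(mc)
    compare_groups(nmj[[mc]], nmj$group, tail = config$tail,
                   reject_outliers = config$outlier_rejection,
                   alpha = config$alpha))
  names(nmj_cmp) <- metric_cols
  # behaviour arm ---------------------------------------------------------
  beh_rows <- list(); beh_speed <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ov <- config$groups[[g]]$behavior
    par_args <- utils::modifyList(
      list(trough_length_mm = config$trough_length_mm,
           trough_width_mm = config$trough_width_mm,
           frame_interval_s = config$frame_interval_s,
           stimulus_start_s = config$stimulus_start_s,
           stimulus_end_s = config$stimulus_end_s,
           stimulated_half = config$stimulated_half,
           duration_s = config$stimulus_end_s),
      if (is.null(ov)) list() else ov)
    params <- do.call(synthetic_behavior_params, par_args)
    sd_g <- derive_seed(500L + gi)
    log_msg("[simulate-behavior] group=%s seed=%d", g, sd_g)
    sim <- generate_behavior(params, seed = sd_g)
    sp <- swim_speed(sim$tracks)
    sp$group <- g
    beh_speed[[g]] <- sp
    beh_rows[[g]] <- data.frame(
      group = g,
      percent_down = percent_down(sim$tracks, "stimulus"),
      percent_down_baseline = percent_down(sim$tracks, "baseline"),
      mean_speed_mm_s = mean(sp$mean_speed_mm_s),
      n_larvae = nrow(sp))
  }
  behavior <- do.call(rbind, beh_rows); rownames(behavior) <- NULL
  speed_all <- do.call(rbind, beh_speed); rownames(speed_all) <- NULL
  beh_tests <- if (length(groups) >= 2)
    compare_groups(speed_all$mean_speed_mm_s, speed_all$group,
                   tail = config$tail,
                   reject_outliers = config$outlier_rejection,
                   alpha = config$alpha)
  # outputs ---------------------------------------------------------------
  paths <- c(nmj = file.path(out_dir, "nmj_metrics.csv"),
             behavior = file.path(out_dir, "behavior_group_metrics.csv"),
             speed = file.path(out_dir, "swim_speed_per_larva.csv"))
  write_metrics(nmj, paths["nmj"])
  write_metrics(behavior, paths["behavior"])
  write_metrics(speed_all, paths["speed"])
  manifest <- list(
    package = "zfcipn",
    version = as.character(utils::packageVersion("zfcipn")),
    seed = seed,
    config = unclass(config),
    outputs = lapply(unname(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  log_msg("[run-all] wrote %d output file(s) to %s", length(paths) + 1L,
          out_dir)
  structure(list(nmj_metrics = nmj, nmj_comparison = nmj_cmp,
                 behavior = behavior, behavior_tests = beh_tests,
                 swim_speed = speed_all,
                 manifest = manifest, out_dir = out_dir),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n== NMJ metrics (per image) ==\n")
  print.data.frame(x$nmj_metrics, digits = 3, row.names = FALSE)
  cat("\n== Behaviour (per group) ==\n")
  print.data.frame(x$behavior, digits = 3, row.names = FALSE)
  cat("\n== M1 group comparison ==\n")
  print(x$nmj_comparison$M1)
  cat(sprintf("\noutputs in %s\n", x$out_dir))
  invisible(x)
}
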