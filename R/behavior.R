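#' Larval trajectory set for the moving-bar plate assay
#'
#' Wraps per-larva position tracks with the trough geometry and stimulus
#' protocol: larvae swim in an agarose trough imaged over a screen that
#' shows a white background (baseline) and then a red bar moving under one
#' half of the trough. The trough long axis is `y` (mm, 0 at the "lower"
#' end); the midline at `trough_length_mm / 2` splits the lower and upper
#' halves.
#'
#' @param tracks data.frame with columns `larva_id`, `frame`, `time_s`,
#'   `x_mm`, `y_mm` (positions may be `NA` for lost-tracking frames).
#' @param trough_length_mm,trough_width_mm trough dimensions (y, x), mm.
#' @param stimulus_start_s,stimulus_end_s stimulus window, seconds.
#' @param stimulated_half `"lower"` or `"upper"`: the half under which the
#'   bar moves.
#' @param frame_interval_s time between frames, seconds.
#' @return An object of class `trajectory_set` (a data.frame with geometry
#'   and stimulus attributes).
#' @export
trajectory_set <- function(tracks, trough_length_mm, trough_width_mm,
                           stimulus_start_s, stimulus_end_s,
                           stimulated_half = c("upper", "lower"),
                           frame_interval_s = 1) {
  stimulated_half <- match.arg(stimulated_half)
  need <- c("larva_id", "frame", "time_s", "x_mm", "y_mm")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0)
    stop("tracks missing required column(s): ", paste(miss, collapse = ", "))
  if (trough_length_mm <= 0 || trough_width_mm <= 0 || frame_interval_s <= 0)
    stop("geometry and frame interval must be positive")
  if (stimulus_end_s < stimulus_start_s)
    stop("stimulus window must have positive length")
  bad <- which(!is.na(tracks$y_mm) &
                 (tracks$y_mm < 0 | tracks$y_mm > trough_length_mm |
                    tracks$x_mm < 0 | tracks$x_mm > trough_width_mm))
  if (length(bad) > 0)
    stop(sprintf("position out of trough bounds at row %d", bad[1]))
  ord <- order(tracks$larva_id, tracks$frame)
  tracks <- tracks[ord, need]
  dup_t <- tapply(tracks$time_s, tracks$larva_id,
                  function(t) any(diff(t) <= 0))
  if (any(unlist(dup_t), na.rm = TRUE))
    stop("time must be strictly increasing within each larva")
  structure(tracks,
            trough = list(length_mm = trough_length_mm,
                          width_mm = trough_width_mm,
                          midline_mm = trough_length_mm / 2),
            stimulus = list(start_s = stimulus_start_s,
                            end_s = stimulus_end_s,
                            stimulated_half = stimulated_half),
            frame_interval_s = frame_interval_s,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  st <- attr(x, "stimulus"); tr <- attr(x, "trough")
  cat(sprintf(
    "<trajectory_set> %d larva(e), %d frames, trough %.3g x %.3g mm,\n  stimulus %gs-%gs under the %s half\n",
    length(unique(x$larva_id)), length(unique(x$frame)),
    tr$length_mm, tr$width_mm, st$start_s, st$end_s, st$stimulated_half))
  invisible(x)
}

#' @export
plot.trajectory_set <- function(x, max_larvae = 10, ...) {
  tr <- attr(x, "trough")
  ids <- unique(x$larva_id)
  ids <- ids[seq_len(min(length(ids), max_larvae))]
  graphics::plot(NA, xlim = c(0, tr$width_mm), ylim = c(0, tr$length_mm),
                 xlab = "x (mm)", ylab = "y (mm)", asp = 1,
                 main = "Larval trajectories", ...)
  graphics::abline(h = tr$midline_mm, lty = 2, col = "grey50")
  for (i in seq_along(ids)) {
    tt <- x[x$larva_id == ids[i], ]
    graphics::lines(tt$x_mm, tt$y_mm, col = grDevices::hcl.colors(length(ids))[i])
  }
  invisible(x)
}

# frame times falling in the requested analysis window
window_frames <- function(tracks, window) {
  st <- attr(tracks, "stimulus")
  tm <- tracks$time_s
  if (identical(window, "stimulus")) {
    tm >= st$start_s & tm <= st$end_s
  } else if (identical(window, "baseline")) {
    tm < st$start_s
  } else if (identical(window, "all")) {
    rep(TRUE, length(tm))
  } else stop("unknown window: ", window)
}

#' Stimulus-avoidance statistic: percent of larvae "down"
#'
#' For every frame in the window, the fraction of tracked larvae in the
#' trough half NOT containing the moving bar is computed; the statistic is
#' 100 times the mean of these per-frame fractions. Avoidance of the bar
#' pushes the value above 50. Larvae exactly on the midline are counted as
#' in the stimulated half, biasing against detecting avoidance
#' (conservative).
#'
#' @param tracks a [trajectory_set()].
#' @param window `"stimulus"` (default), `"baseline"`, or `"all"`.
#' @return Percent in \[0, 100\].
#' @export
percent_down <- function(tracks, window = "stimulus") {
  stopifnot(inherits(tracks, "trajectory_set"))
  sel <- window_frames(tracks, window) & !is.na(tracks$y_mm)
  if (!any(sel)) stop("no tracked frames in the requested window")
  mid <- attr(tracks, "trough")$midline_mm
  up <- attr(tracks, "stimulus")$stimulated_half == "upper"
  y <- tracks$y_mm[sel]
  down <- if (up) y < mid else y > mid     # ties -> stimulated half
  frac <- tapply(down, tracks$frame[sel], mean)
  100 * mean(frac)
}

#' Per-larva mean swim speed
#'
#' Sums Euclidean displacements between consecutive frames and divides by
#' the elapsed time, per larva. Pairs with a lost position on either side
#' are skipped; larvae missing more than half their frames, or with fewer
#' than two usable frames, are dropped with a warning.
#'
#' @param tracks a [trajectory_set()].
#' @param window `"all"` (default; the assay does not restrict speed to the
#'   stimulus period), `"stimulus"`, or `"baseline"`.
#' @return data.frame with `larva_id`, `mean_speed_mm_s`, `n_segments`.
#' @export
swim_speed <- function(tracks, window = "all") {
  stopifnot(inherits(tracks, "trajectory_set"))
  sel <- window_frames(tracks, window)
  tt <- tracks[sel, , drop = FALSE]
  n_frames <- length(unique(tt$frame))
  ids <- unique(tt$larva_id)
  res <- lapply(ids, function(id) {
    d <- tt[tt$larva_id == id, ]
    ok <- !is.na(d$x_mm) & !is.na(d$y_mm)
    if (sum(ok) < n_frames / 2) {
      warning(sprintf("larva %s missing >50%% of frames: dropped", id))
      return(NULL)
    }
    d <- d[ok, ]
    # consecutive-frame pairs only: a lost frame breaks the pair
    consec <- which(diff(d$frame) == 1L)
    if (length(consec) == 0L) {
      warning(sprintf("larva %s has <2 usable consecutive frames: excluded", id))
      return(NULL)
    }
    dx <- d$x_mm[consec + 1L] - d$x_mm[consec]
    dy <- d$y_mm[consec + 1L] - d$y_mm[consec]
    dt <- d$time_s[consec + 1L] - d$time_s[consec]
    data.frame(larva_id = id,
               mean_speed_mm_s = sum(sqrt(dx^2 + dy^2)) / sum(dt),
               n_segments = length(consec))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    stop("no larva had enough tracked frames for a speed estimate")
  rownames(out) <- NULL
  out
}

#' Group means with standard errors
#'
#' @param values numeric vector of per-larva (or per-image) metric values.
#' @param groups group labels, same length.
#' @return data.frame with `group`, `n`, `mean`, `se` (sample SD / sqrt(n);
#'   `NA` when `n = 1`). `NA` values are dropped per group.
#' @export
summarize_groups <- function(values, groups) {
  if (length(values) != length(groups))
    stop("`values` and `groups` must have the same length")
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  if (length(values) == 0L) stop("no non-missing values")
  gl <- unique(groups)
  out <- do.call(rbind, lapply(gl, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
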