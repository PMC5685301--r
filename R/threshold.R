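#' Kapur maximum-entropy threshold of a 256-bin histogram
#'
#' Selects the threshold `t` maximizing the sum of Shannon entropies of the
#' background (bins `<= t`) and foreground (bins `> t`) partitions of the
#' normalized histogram, the criterion behind the MaxEntropy auto-threshold
#' familiar from ImageJ/Fiji. Zero-probability bins contribute nothing;
#' candidate thresholds leaving either partition empty are not considered.
#' Ties are broken toward the smallest `t`.
#'
#' @param counts integer vector of 256 histogram counts for intensity bins
#'   0..255 (use [histogram_256()] to bin an image).
#' @return The selected threshold as a bin value in `0:255`: pixels in bins
#'   strictly greater than the returned value are foreground.
#' @references Kapur, Sahoo & Wong (1985) A new method for gray-level
#'   picture thresholding using the entropy of the histogram.
#' @export
kapur_threshold <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 256L || anyNA(counts) || any(counts < 0))
    stop("`counts` must be 256 non-negative histogram counts")
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied intensity levels")
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  w <- cumsum(p)          # background mass up to bin t (index t+1)
  s <- cumsum(plogp)
  wt <- sum(p); st <- sum(plogp)
  # background entropy: log(w) - s/w for bins <= t; foreground analogous
  hb <- ifelse(w > 0, log(w) - s / w, 0)
  wf <- wt - w; sf <- st - s
  hf <- ifelse(wf > 0, log(wf) - sf / wf, 0)
  crit <- hb + hf
  valid <- w > 0 & wf > 0
  if (!any(valid))
    stop("degenerate histogram: no threshold separates two partitions")
  crit[!valid] <- -Inf
  # smallest t attaining the maximum (allow for floating-point ties)
  best <- max(crit[valid])
  which(valid & crit >= best - 1e-12)[1] - 1L
}

#' Bin an image into a 256-level histogram
#'
#' 8-bit images are tabulated on their native 0..255 levels. Deeper images
#' are linearly binned from their observed min..max range into 256 levels,
#' matching common auto-threshold practice; use [native_threshold()] to map
#' the resulting bin threshold back to the native intensity scale.
#'
#' @param pixels numeric vector or matrix of integer intensities.
#' @param bit_depth 8 or 16.
#' @return A list with `counts` (length-256 integer vector), and the
#'   binning parameters `lo` and `bin_width` needed to invert the binning.
#' @export
histogram_256 <- function(pixels, bit_depth = 8) {
  v <- as.numeric(pixels)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no pixels to histogram")
  if (bit_depth == 8) {
    counts <- tabulate(v + 1, nbins = 256L)
    list(counts = counts, lo = 0, bin_width = 1)
  } else {
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      counts <- integer(256L); counts[1] <- length(v)
      return(list(counts = counts, lo = lo, bin_width = 1))
    }
    bw <- (hi - lo + 1) / 256
    bins <- pmin(255L, as.integer(floor((v - lo) / bw)))
    list(counts = tabulate(bins + 1, nbins = 256L), lo = lo, bin_width = bw)
  }
}

#' Map a 256-bin threshold back to the native intensity scale
#'
#' Returns the largest native intensity belonging to bin `t`, so that the
#' native mask rule `intensity > native_threshold` selects exactly the
#' pixels in bins `> t`.
#'
#' @param t bin threshold in `0:255` as returned by [kapur_threshold()].
#' @param hist the binning descriptor from [histogram_256()].
#' @return Native-scale threshold (numeric).
#' @export
native_threshold <- function(t, hist) {
  # upper edge of bin t: largest integer v with floor((v - lo)/bw) == t
  hist$lo + ceiling((t + 1) * hist$bin_width) - 1
}

#' Threshold a projection with the Kapur maximum-entropy criterion
#'
#' Convenience wrapper: histograms the in-domain pixels, runs
#' [kapur_threshold()], and maps back to the native scale.
#'
#' @param image an `nmj_projection`.
#' @return Native-scale threshold suitable for [apply_threshold_mask()].
#' @export
kapur_threshold_image <- function(image) {
  stopifnot(inherits(image, "nmj_projection"))
  h <- histogram_256(image$pixels[image$domain], image$bit_depth)
  native_threshold(kapur_threshold(h$counts), h)
}
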