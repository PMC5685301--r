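# Independent oracles and fixture builders used across the suite.

# Build a single-slice projection from a plain matrix through the public API.
proj_from_matrix <- function(m, bit_depth = 8, pixel_size_xy = 1) {
  max_z_projection(image_stack(m, bit_depth = bit_depth,
                               pixel_size_xy = pixel_size_xy))
}

# Masked projection with mask rule "intensity > 0" (identity masking for
# already-sparse matrices).
masked_proj <- function(m, pixel_size_xy = 1, bit_depth = 8) {
  apply_threshold_mask(proj_from_matrix(m, bit_depth, pixel_size_xy), 0)
}

# Brute-force Kapur oracle: evaluates the two partition entropies from the
# definition for every candidate threshold, independent of the vectorized
# implementation.
kapur_oracle <- function(counts) {
  p <- counts / sum(counts)
  best_t <- NA_integer_; best <- -Inf
  for (t in 0:255) {
    wb <- sum(p[1:(t + 1)])
    wf <- 1 - wb
    if (wb <= 0 || wf <= 0) next
    hb <- 0
    for (i in 1:(t + 1)) if (p[i] > 0) {
      q <- p[i] / wb; hb <- hb - q * log(q)
    }
    hf <- 0
    if (t < 255) for (i in (t + 2):256) if (p[i] > 0) {
      q <- p[i] / wf; hf <- hf - q * log(q)
    }
    if (hb + hf > best + 1e-12) { best <- hb + hf; best_t <- t }
  }
  best_t
}

# Connected-component oracle via igraph: 8-neighbour pixel graph.
components_oracle <- function(fg) {
  idx <- which(fg)
  if (length(idx) == 0) return(list(n = 0L, sizes = integer()))
  nr <- nrow(fg)
  rc <- arrayInd(idx, dim(fg))
  key <- function(r, c) (c - 1L) * nr + r
  edges <- integer(0)
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  pos <- match(idx, idx)
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  for (i in seq_along(idx)) {
    r <- rc[i, 1]; c <- rc[i, 2]
    for (k in 1:8) {
      rr <- r + off[k, 1]; cc <- c + off[k, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(fg) && fg[rr, cc]) {
        j <- get(as.character(key(rr, cc)), envir = lookup)
        if (j > i) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  list(n = comp$no, sizes = sort(as.integer(comp$csize)))
}

# Iterative modified-Thompson-tau oracle, written from the rule definition.
tau_oracle <- function(x, alpha = 0.05) {
  removed <- numeric(0)
  while (length(x) >= 3) {
    n <- length(x); s <- stats::sd(x)
    if (s == 0) break
    tq <- stats::qt(1 - alpha / 2, n - 2)
    tau <- tq * (n - 1) / (sqrt(n) * sqrt(n - 2 + tq^2))
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    if (dev[i] > tau * s) { removed <- c(removed, x[i]); x <- x[-i] }
    else break
  }
  list(kept = x, removed = removed)
}

# Pooled two-sample t oracle from the textbook formula.
pooled_t_oracle <- function(a, b, tail = "two", direction = "greater") {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- if (tail == "two") 2 * stats::pt(-abs(t), df)
  else if (direction == "greater") stats::pt(t, df, lower.tail = FALSE)
  else stats::pt(t, df)
  list(statistic = t, df = df, p_value = p)
}

# Random sparse blob mask for particle-analysis property tests.
random_blob_mask <- function(nr = 40, nc = 40, n_seeds = 8, grow = 20) {
  m <- matrix(FALSE, nr, nc)
  pts <- cbind(sample.int(nr, n_seeds, replace = TRUE),
               sample.int(nc, n_seeds, replace = TRUE))
  m[pts] <- TRUE
  for (g in seq_len(grow)) {
    idx <- which(m)
    rc <- arrayInd(idx, dim(m))
    step <- rc[sample.int(nrow(rc), max(1, nrow(rc) %/% 3)), , drop = FALSE]
    step[, 1] <- pmin(pmax(step[, 1] + sample(c(-1L, 0L, 1L),
                                              nrow(step), TRUE), 1L), nr)
    step[, 2] <- pmin(pmax(step[, 2] + sample(c(-1L, 0L, 1L),
                                              nrow(step), TRUE), 1L), nc)
    m[step] <- TRUE
  }
  m
}

# Wrap a logical matrix as a binary_mask through the public API: encode the
# mask as a 0/1 image thresholded at 0.
mask_from_logical <- function(fg, pixel_size_xy = 1) {
  masked_proj(fg * 1L, pixel_size_xy = pixel_size_xy)$mask
}
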