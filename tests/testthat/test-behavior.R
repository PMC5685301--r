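make_tracks <- function(df, L = 10, W = 4, start = 0, end = 10,
                        half = "upper") {
  trajectory_set(df, trough_length_mm = L, trough_width_mm = W,
                 stimulus_start_s = start, stimulus_end_s = end,
                 stimulated_half = half)
}

test_that("percent_down counts occupancy of the unstimulated half", {
  # all larvae in the unstimulated (lower) half throughout -> 100
  df <- expand.grid(larva_id = c("a", "b"), frame = 1:3)
  df$time_s <- df$frame - 1
  df$x_mm <- 1; df$y_mm <- 2      # below midline 5
  expect_equal(percent_down(make_tracks(df)), 100)

  # hand-built 2-larvae 2-frame set vs hand count:
  # frame1: a down, b up -> 0.5; frame2: both up -> 0 => mean 25%
  df2 <- data.frame(larva_id = rep(c("a", "b"), each = 2),
                    frame = c(1, 2, 1, 2), time_s = c(0, 1, 0, 1),
                    x_mm = 1, y_mm = c(2, 8, 9, 7))
  expect_equal(percent_down(make_tracks(df2)), 25)

  # midline ties count as stimulated (conservative)
  df3 <- data.frame(larva_id = "a", frame = 1, time_s = 0, x_mm = 1, y_mm = 5)
  expect_equal(percent_down(make_tracks(df3)), 0)

  # stimulated_half = lower flips the reading
  expect_equal(percent_down(make_tracks(df2, half = "lower")), 75)

  # empty window errors
  expect_error(percent_down(make_tracks(df2, start = 50, end = 60)),
               "no tracked frames")
})

test_that("percent_down is invariant to id relabelling and trough reflection", {
  set.seed(21)
  n <- 8; nf <- 20
  df <- data.frame(larva_id = rep(letters[1:n], each = nf),
                   frame = rep(1:nf, n),
                   time_s = rep(0:(nf - 1), n),
                   x_mm = runif(n * nf, 0, 4),
                   y_mm = runif(n * nf, 0, 10))
  base <- percent_down(make_tracks(df))

  rel <- df; rel$larva_id <- rep(sprintf("z%02d", n:1), each = nf)
  expect_equal(percent_down(make_tracks(rel)), base)

  refl <- df; refl$y_mm <- 10 - refl$y_mm
  expect_equal(percent_down(make_tracks(refl, half = "lower")), base)
})

test_that("swim speed is total path length over elapsed time per larva", {
  # straight line, 1 mm per 1 s frame
  df <- data.frame(larva_id = "a", frame = 1:5, time_s = 0:4,
                   x_mm = 0:4, y_mm = 1)
  expect_equal(swim_speed(make_tracks(df, W = 10))$mean_speed_mm_s, 1)

  # stationary larva
  df0 <- data.frame(larva_id = "a", frame = 1:5, time_s = 0:4,
                    x_mm = 2, y_mm = 2)
  expect_equal(swim_speed(make_tracks(df0))$mean_speed_mm_s, 0)

  # random walk vs displacement-sum oracle
  set.seed(14)
  xs <- cumsum(c(2, runif(9, -0.2, 0.2))); ys <- cumsum(c(5, runif(9, -0.2, 0.2)))
  dfr <- data.frame(larva_id = "a", frame = 1:10, time_s = seq(0, 4.5, 0.5),
                    x_mm = xs, y_mm = ys)
  oracle <- sum(sqrt(diff(xs)^2 + diff(ys)^2)) / 4.5
  expect_equal(swim_speed(make_tracks(dfr))$mean_speed_mm_s, oracle)

  # lost frames are skipped pairwise; heavily lost larvae are dropped
  dfl <- data.frame(larva_id = "a", frame = 1:6, time_s = 0:5,
                    x_mm = c(0, 1, NA, 3, 4, 5), y_mm = 1)
  sp <- swim_speed(make_tracks(dfl, W = 10))
  expect_equal(sp$n_segments, 3)   # pairs (1,2), (4,5), (5,6)
  expect_equal(sp$mean_speed_mm_s, 1)

  dfdrop <- data.frame(
    larva_id = rep(c("ok", "lost"), each = 6), frame = rep(1:6, 2),
    time_s = rep(0:5, 2),
    x_mm = c(0:5, 0, NA, NA, NA, NA, 5), y_mm = 1)
  expect_warning(sp2 <- swim_speed(make_tracks(dfdrop, W = 10)), "missing >50%")
  expect_equal(sp2$larva_id, "ok")
})

test_that("group summaries give mean and standard error", {
  s <- summarize_groups(c(2, 4), c("g", "g"))
  expect_equal(s$mean, 3); expect_equal(s$se, 1)

  s2 <- summarize_groups(rep(7, 5), rep("g", 5))
  expect_equal(s2$se, 0)

  # n = 1 -> missing se
  s3 <- summarize_groups(c(1, 2, 9), c("a", "a", "b"))
  expect_true(is.na(s3$se[s3$group == "b"]))

  set.seed(3)
  v <- rnorm(12); g <- rep(c("a", "b"), 6)
  s4 <- summarize_groups(v, g)
  expect_equal(s4$mean[s4$group == "a"], mean(v[g == "a"]))
  expect_equal(s4$se[s4$group == "b"],
               sd(v[g == "b"]) / sqrt(6))
})

test_that("trajectory validation catches bad input", {
  df <- data.frame(larva_id = "a", frame = 1:2, time_s = 0:1,
                   x_mm = c(1, 99), y_mm = 1)
  expect_error(make_tracks(df), "out of trough bounds")
  df2 <- data.frame(larva_id = "a", frame = 1:2, time_s = c(1, 1),
                    x_mm = 1, y_mm = 1)
  expect_error(make_tracks(df2), "strictly increasing")
  expect_error(make_tracks(data.frame(larva_id = "a", frame = 1)),
               "missing required column")
})
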