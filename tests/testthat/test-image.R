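test_that("max projection takes the pixelwise maximum over selected slices", {
  # single slice: identity
  m <- matrix(c(3L, 7L, 0L, 255L), 2, 2)
  st <- image_stack(array(m, c(2, 2, 1)))
  expect_identical(max_z_projection(st, 1)$pixels, apply(array(m, c(2, 2, 1)), 1:2, max))

  # two slices with known values
  vox <- array(0L, c(1, 1, 2)); vox[1, 1, ] <- c(3L, 7L)
  expect_equal(max_z_projection(image_stack(vox))$pixels[1, 1], 7)

  # random 5-slice stack vs brute-force per-pixel loop
  set.seed(101)
  vox <- array(sample(0:255, 6 * 5 * 5, TRUE), c(6, 5, 5))
  proj <- max_z_projection(image_stack(vox), 2:4)
  brute <- matrix(0L, 6, 5)
  for (r in 1:6) for (c in 1:5) {
    mx <- 0L
    for (k in 2:4) if (vox[r, c, k] > mx) mx <- vox[r, c, k]
    brute[r, c] <- mx
  }
  expect_equal(proj$pixels, brute)

  # dominance + idempotence properties
  for (k in 2:4) expect_true(all(proj$pixels >= vox[, , k]))
  st2 <- image_stack(array(proj$pixels, c(dim(proj$pixels), 1)))
  expect_equal(max_z_projection(st2)$pixels, proj$pixels)

  # errors
  expect_error(max_z_projection(image_stack(vox), integer(0)), "at least one")
  expect_error(max_z_projection(image_stack(vox), 7), "out of range")
})

test_that("ROI cropping removes pixels from the domain without zeroing them", {
  set.seed(7)
  m <- matrix(sample(0:255, 100, TRUE), 10, 10)
  proj <- proj_from_matrix(m)

  # retain over whole image = identity domain
  whole <- crop_roi(proj, rect_roi(1, 10, 1, 10, "retain"))
  expect_true(all(whole$domain))

  # exclude half of a uniform image: percent positive unchanged
  u <- masked_proj(matrix(5L, 10, 10))
  pct_full <- analyze_particles(u$mask)$percent_positive_pixels
  half <- crop_roi(u$masked, rect_roi(1, 5, 1, 10, "exclude"))
  u$mask$domain <- half$domain
  expect_equal(analyze_particles(u$mask)$percent_positive_pixels, pct_full)
  expect_equal(analyze_particles(u$mask)$domain_pixels, 50)

  # excluding the stripe holding all signal zeroes the percent metric
  s <- matrix(0L, 10, 10); s[3, ] <- 200L
  sm <- masked_proj(s)
  stripe <- crop_roi(sm$masked, rect_roi(3, 3, 1, 10, "exclude"))
  sm$mask$domain <- stripe$domain
  expect_equal(analyze_particles(sm$mask)$percent_positive_pixels, 0)

  # cropped-out intensities are not used, but also not destroyed
  expect_equal(stripe$pixels[3, 4], 200)

  expect_error(crop_roi(proj, rect_roi(1, 10, 1, 10, "exclude")),
               "empty analysis domain")
  expect_error(rect_roi(5, 4, 1, 10), "start <= end")
})

test_that("Kapur threshold maximizes partition entropy with smallest-t ties", {
  # two-level histogram: all t in [10, 199] tie; smallest wins
  h <- integer(256); h[10 + 1] <- 40; h[200 + 1] <- 60
  expect_identical(kapur_threshold(h), 10L)
  expect_identical(kapur_oracle(h), 10L)

  # degenerate single-level histogram errors
  h1 <- integer(256); h1[50] <- 99
  expect_error(kapur_threshold(h1), "degenerate")

  # random histograms match the exhaustive oracle
  set.seed(42)
  for (i in 1:60) {
    h <- as.integer(rpois(256, lambda = rexp(256, 1 / 20)))
    if (sum(h > 0) < 2) next
    expect_identical(kapur_threshold(h), kapur_oracle(h))
  }
})

test_that("16-bit images are min-max binned and thresholds map back", {
  set.seed(9)
  v <- matrix(as.integer(round(runif(400, 1000, 30000))), 20, 20)
  h <- histogram_256(v, bit_depth = 16)
  expect_equal(sum(h$counts), 400)
  t_bin <- kapur_threshold(h$counts)
  t_nat <- native_threshold(t_bin, h)
  # the native rule selects exactly the pixels in bins above t_bin
  bins <- pmin(255, floor((as.vector(v) - h$lo) / h$bin_width))
  expect_equal(as.vector(v) > t_nat, bins > t_bin)
})

test_that("threshold masking keeps intensities above t and zeroes the rest", {
  m <- matrix(c(5L, 20L, 10L, 0L), 2, 2)
  out <- apply_threshold_mask(proj_from_matrix(m), 9)
  expect_identical(out$mask$pixels, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_equal(out$masked$pixels, matrix(c(0, 20, 10, 0), 2, 2))
  # threshold at max intensity leaves an empty mask
  expect_false(any(apply_threshold_mask(proj_from_matrix(m), 20)$mask$pixels))
  # minimum legal threshold 0 keeps all pixels > 0
  expect_equal(sum(apply_threshold_mask(proj_from_matrix(m), 0)$mask$pixels), 3)
  expect_error(apply_threshold_mask(proj_from_matrix(m), -1), "within")
})

test_that("Manders coefficients follow their defining ratios", {
  r <- masked_proj(matrix(c(10L, 0L, 10L, 0L), 1, 4))$masked
  g <- masked_proj(matrix(c(5L, 5L, 0L, 0L), 1, 4))$masked
  mm <- manders_coefficients(r, g)
  expect_equal(mm$M1, 0.5)
  expect_equal(mm$M2, 0.5)

  # identical nonzero channels: full overlap
  set.seed(1)
  a <- masked_proj(matrix(sample(1:200, 64, TRUE), 8, 8))$masked
  mm <- manders_coefficients(a, a)
  expect_equal(mm$M1, 1); expect_equal(mm$M2, 1)

  # disjoint supports
  d1 <- matrix(0L, 4, 4); d1[1:2, ] <- 7L
  d2 <- matrix(0L, 4, 4); d2[3:4, ] <- 9L
  mm <- manders_coefficients(masked_proj(d1)$masked, masked_proj(d2)$masked)
  expect_equal(mm$M1, 0); expect_equal(mm$M2, 0)
})

test_that("empty channels give NA coefficients with a warning", {
  set.seed(2)
  a <- masked_proj(matrix(sample(1:50, 16, TRUE), 4, 4))$masked
  z <- masked_proj(matrix(0L, 4, 4))$masked
  expect_warning(mm <- manders_coefficients(z, a), "M1 undefined")
  expect_true(is.na(mm$M1))
  expect_equal(mm$M2, 0)  # green has signal but none overlaps empty red
})

test_that("Manders properties: swap symmetry and intensity-scale invariance", {
  set.seed(33)
  for (i in 1:25) {
    r <- matrix(sample(0:120, 100, TRUE), 10, 10)
    g <- matrix(sample(0:120, 100, TRUE), 10, 10)
    mr <- masked_proj(r)$masked; mg <- masked_proj(g)$masked
    ab <- manders_coefficients(mr, mg)
    ba <- manders_coefficients(mg, mr)
    expect_equal(ab$M1, ba$M2)
    expect_equal(ab$M2, ba$M1)
    # positive scaling of both channels leaves M1/M2 unchanged
    sc <- manders_coefficients(masked_proj(r * 2L, bit_depth = 16)$masked,
                               masked_proj(g * 2L, bit_depth = 16)$masked)
    expect_equal(sc$M1, ab$M1)
    expect_equal(sc$M2, ab$M2)
  }
})

test_that("Pearson coefficient matches the product-moment definition", {
  set.seed(11)
  r <- matrix(sample(1:100, 36, TRUE), 6, 6)
  pr <- masked_proj(r)$masked

  g2 <- masked_proj(r * 2L, bit_depth = 16)$masked
  expect_equal(pearson_coefficient(pr, g2), 1)

  ginv <- masked_proj(max(r) - r)$masked
  expect_equal(pearson_coefficient(pr, ginv), -1)

  # random pair vs the two-pass textbook formula
  g <- matrix(sample(0:100, 36, TRUE), 6, 6)
  pg <- masked_proj(g)$masked
  rv <- as.numeric(r); gv <- as.numeric(g)
  num <- sum((rv - mean(rv)) * (gv - mean(gv)))
  den <- sqrt(sum((rv - mean(rv))^2) * sum((gv - mean(gv))^2))
  expect_equal(pearson_coefficient(pr, pg), num / den, tolerance = 1e-12)

  # zero variance -> NA with warning
  const <- masked_proj(matrix(4L, 6, 6))$masked
  expect_warning(pc <- pearson_coefficient(pr, const), "zero variance")
  expect_true(is.na(pc))
})

test_that("particle analysis counts 8-connected components and percent area", {
  # three disjoint 2x2 squares in a 10x10 image
  m <- matrix(0L, 10, 10)
  m[1:2, 1:2] <- 50L; m[5:6, 5:6] <- 90L; m[9:10, 1:2] <- 200L
  ps <- analyze_particles(masked_proj(m)$mask)
  expect_equal(ps$n_particles, 3)
  expect_equal(ps$percent_positive_pixels, 12)
  expect_equal(sort(ps$particles$area_pixels), c(4L, 4L, 4L))

  # diagonal touch merges under 8-connectivity
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(analyze_particles(masked_proj(d)$mask)$n_particles, 1)

  # doubling intensities leaves the particle output unchanged
  ps2 <- analyze_particles(masked_proj(m * 2L, bit_depth = 16)$mask)
  expect_equal(ps2$n_particles, ps$n_particles)
  expect_equal(ps2$percent_positive_pixels, ps$percent_positive_pixels)
  expect_equal(ps2$particles$area_pixels, ps$particles$area_pixels)

  # calibrated areas
  ps_cal <- analyze_particles(mask_from_logical(m > 0, pixel_size_xy = 0.5))
  expect_equal(ps_cal$particles$area_um2, ps_cal$particles$area_pixels * 0.25)

  # empty mask: zero particles, 0 percent
  e <- analyze_particles(masked_proj(matrix(0L, 5, 5))$mask)
  expect_equal(e$n_particles, 0)
  expect_equal(e$percent_positive_pixels, 0)

  # min_area filter drops small particles but not the percent metric
  psf <- analyze_particles(masked_proj(m)$mask, min_area_pixels = 5)
  expect_equal(psf$n_particles, 0)
  expect_equal(psf$percent_positive_pixels, 12)
})

test_that("particle labelling agrees with an independent graph-component oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (i in 1:25) {
    fg <- random_blob_mask(30, 30, n_seeds = sample(2:10, 1))
    ps <- analyze_particles(mask_from_logical(fg))
    orc <- components_oracle(fg)
    expect_equal(ps$n_particles, orc$n)
    expect_equal(sort(ps$particles$area_pixels), orc$sizes)
    expect_equal(ps$percent_positive_pixels, 100 * sum(fg) / length(fg))
  }
})

test_that("axon length is the calibrated polyline length", {
  expect_equal(measure_axon_length(rbind(c(0, 0), c(0, 10)), 0.5), 5)
  sq <- rbind(c(0, 0), c(0, 3), c(3, 3), c(3, 0), c(0, 0))
  expect_equal(measure_axon_length(sq, 1), 12)
  set.seed(5)
  v <- matrix(runif(20, 0, 50), 10, 2)
  expect_equal(measure_axon_length(v, 0.3),
               sum(sqrt(rowSums(diff(v)^2))) * 0.3)
  expect_error(measure_axon_length(rbind(c(0, 0)), 1), ">= 2")
})

test_that("full quantification recovers constructed colocalization exactly", {
  p1 <- synthetic_nmj_params(coloc_fraction = 1, background = 0,
                             gaussian_sd = 0, poisson_noise = FALSE)
  m1 <- quantify_nmj(generate_nmj_stack(p1, seed = 7)$stack,
                     thresholds = c(red = 0, green = 0))
  expect_equal(m1$M1, 1)

  p0 <- synthetic_nmj_params(coloc_fraction = 0, background = 0,
                             gaussian_sd = 0, poisson_noise = FALSE,
                             min_separation_um = 6, n_red_puncta = 20,
                             n_green_clusters = 8)
  m0 <- quantify_nmj(generate_nmj_stack(p0, seed = 7)$stack,
                     thresholds = c(red = 0, green = 0))
  expect_equal(m0$M1, 0)
  expect_equal(m0$M2, 0)
})

test_that("estimated M1 separates high from low true colocalization", {
  hits <- 0L
  n_pairs <- 15L
  for (s in seq_len(n_pairs)) {
    hi <- quantify_nmj(generate_nmj_stack(
      synthetic_nmj_params(coloc_fraction = 0.8), seed = 100 + s)$stack)$M1
    lo <- quantify_nmj(generate_nmj_stack(
      synthetic_nmj_params(coloc_fraction = 0.2), seed = 900 + s)$stack)$M1
    if (hi > lo) hits <- hits + 1L
  }
  expect_gte(hits, n_pairs - 1L)
})

test_that("quantification errors carry the failing stage", {
  st <- image_stack(array(5L, c(4, 4, 2)))
  pair <- two_channel_stack(st, st)
  expect_error(quantify_nmj(pair), "threshold")
})
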