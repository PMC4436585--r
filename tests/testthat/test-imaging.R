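test_that("the band-pass filter maps constants to zero and keeps spots in place", {
  const <- matrix(7, 40, 40)
  expect_lt(max(abs(bandpass(const))), 1e-10)
  img <- matrix(0, 64, 64)
  x0 <- 30.0; y0 <- 25.0
  for (r in 1:64) for (c in 1:64)
    img[r, c] <- 100 * exp(-((r - y0)^2 + (c - x0)^2) / (2 * 1.3^2))
  f <- bandpass(img)
  peak <- which(f == max(f), arr.ind = TRUE)
  expect_lte(abs(peak[1, "row"] - y0), 0.5)
  expect_lte(abs(peak[1, "col"] - x0), 0.5)
  expect_error(bandpass(img, object_w_px = 1, noise_sigma_px = 1), ">=")
})

test_that("a linear background ramp does not defeat spot detection", {
  img <- matrix(0, 64, 64)
  for (r in 1:64) for (c in 1:64)
    img[r, c] <- 200 * exp(-((r - 32)^2 + (c - 20)^2) / (2 * 1.3^2))
  ramp <- outer(seq(0, 60, length.out = 64), rep(1, 64))
  det_clean <- locate_particles(bandpass(img))
  det_ramp <- locate_particles(bandpass(img + ramp))
  expect_equal(nrow(det_clean), 1)
  expect_equal(nrow(det_ramp), 1)
  expect_lt(abs(det_ramp$x_px - det_clean$x_px), 0.2)
  expect_lt(abs(det_ramp$y_px - det_clean$y_px), 0.2)
})

test_that("sub-pixel centroids localize a symmetric Gaussian spot", {
  img <- matrix(0, 64, 64)
  x0 <- 41.7; y0 <- 20.3
  for (r in 1:64) for (c in 1:64)
    img[r, c] <- 150 * exp(-((r - y0)^2 + (c - x0)^2) / (2 * 1.3^2))
  det <- locate_particles(bandpass(img))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - x0), 0.1)
  expect_lt(abs(det$y_px - y0), 0.1)
  expect_gt(det$m0, 0)
  expect_gt(det$Rg2, 0)
})

test_that("empty scenes yield empty particle sets", {
  sp <- scene_spec(n_vesicles = 0, seed = 1)
  sc <- render_vesicle_scene(sp)
  det <- detect_vesicles(sc, channel = "ch405")
  expect_equal(nrow(det), 0)
})

test_that("the detector is translation-equivariant for integer shifts", {
  sp <- scene_spec(image_shape = c(128, 128), n_vesicles = 15,
                   photon_scale = Inf, seed = 9)
  sc <- render_vesicle_scene(sp)
  img <- sc$channels$ch561
  dx <- 5L; dy <- 3L
  shifted <- matrix(sp$background_level, 128, 128)
  shifted[(1 + dy):128, (1 + dx):128] <- img[1:(128 - dy), 1:(128 - dx)]
  d1 <- locate_particles(bandpass(img))
  d2 <- locate_particles(bandpass(shifted))
  # compare spots that remain well inside the frame after the shift
  inner <- d1[d1$x_px < 128 - dx - 8 & d1$y_px < 128 - dy - 8, ]
  m <- match_particles(data.frame(x_px = d2$x_px - dx, y_px = d2$y_px - dy),
                       inner, max_dist_px = 0.2)
  expect_equal(m$recall, 1)
  expect_lt(max(m$matches$dist), 0.05)
})

test_that("detection performance on default-SNR scenes meets spec", {
  recalls <- fps <- rmses <- numeric(5)
  for (s in 1:5) {
    sc <- render_vesicle_scene(scene_spec(seed = 100 + s))
    det <- detect_vesicles(sc, channel = "ch561")
    m <- match_particles(det, sc$truth)
    recalls[s] <- m$recall; fps[s] <- m$false_positive_rate
    rmses[s] <- m$rmse_px
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(fps), 0.02)
  expect_lt(mean(rmses), 0.2)
})

test_that("per-vesicle ratios invert the forward model exactly without noise", {
  sp <- scene_spec(n_vesicles = 10, photon_scale = Inf, min_sep_factor = 10,
                   seed = 4)
  sc <- render_vesicle_scene(sp)
  det <- detect_vesicles(sc, channel = "ch561")
  rat <- measure_ratio(sc$channels, det)
  m <- match_particles(det, sc$truth)
  truth_r <- predict_ratio(sp$ratio_line, sc$truth$pH[m$matches$truth])
  expect_equal(rat$R[m$matches$det], truth_r, tolerance = 1e-12)
  # and pH round trip through the calibration line is exact
  ph <- ratios_to_pH(rat$R, sp$ratio_line)
  expect_equal(ph$pH[m$matches$det], sc$truth$pH[m$matches$truth],
               tolerance = 1e-9)
})

test_that("ratio arithmetic and the non-positive-denominator guard hold", {
  ch <- list(ch405 = matrix(0, 21, 21), ch488 = matrix(0, 21, 21))
  for (r in 1:21) for (c in 1:21) {
    g <- exp(-((r - 11)^2 + (c - 11)^2) / (2 * 1.3^2))
    ch$ch405[r, c] <- 160 * g
    ch$ch488[r, c] <- 200 * g
  }
  parts <- data.frame(x_px = 11, y_px = 11)
  rat <- measure_ratio(ch, parts, background = "none")
  expect_equal(rat$R, 1.25, tolerance = 1e-9)
  # zero 405 signal: excluded and logged
  ch0 <- list(ch405 = matrix(0, 21, 21), ch488 = ch$ch488)
  rat0 <- measure_ratio(ch0, parts, background = "none")
  expect_equal(nrow(rat0), 0)
  expect_equal(nrow(attr(rat0, "excluded")), 1)
})

test_that("calibration lines fit exactly on exact data and reject rank deficiency", {
  ph <- c(5, 6.5, 8); r <- 0.5 * ph - 2.0
  line <- fit_calibration_line(ph, r)
  expect_equal(line$slope, 0.5, tolerance = 1e-12)
  expect_equal(line$intercept, -2.0, tolerance = 1e-12)
  expect_equal(line$pH_lo, 5); expect_equal(line$pH_hi, 8)
  expect_error(fit_calibration_line(c(6, 6, 6), c(1, 1.1, 0.9)),
               "rank")
  conv <- ratios_to_pH(1.25, line)
  expect_equal(conv$pH, 6.5, tolerance = 1e-12)
  expect_false(conv$extrapolated)
  conv0 <- ratios_to_pH(line$intercept, line)   # pH 0, far below range
  expect_true(conv0$extrapolated)
})

test_that("simulated calibration series are monotone and shrink the fit SE with replicates", {
  tmpl <- scene_spec(image_shape = c(96, 96), n_vesicles = 15)
  ph_list <- c(5.5, 6.0, 6.5, 7.0, 7.5)
  series <- simulate_calibration_series(ph_list, tmpl, seed = 3)
  mean_r <- vapply(series, function(sc) {
    det <- detect_vesicles(sc, channel = "ch561")
    mean(measure_ratio(sc$channels, det)$R)
  }, 1)
  expect_true(all(diff(mean_r) > 0))
  expect_error(simulate_calibration_series(4.2, tmpl), "validity")
  # a single pH cannot support a line fit
  expect_error(fit_calibration_line(rep(6.0, 3), c(1, 1.01, 0.99)), "rank")
  # replicates shrink the slope standard error
  fit1 <- fit_calibration_line(ph_list, mean_r)
  series6 <- simulate_calibration_series(ph_list, tmpl, n_replicates = 6,
                                         seed = 3)
  r6 <- vapply(series6, function(sc) {
    det <- detect_vesicles(sc, channel = "ch561")
    mean(measure_ratio(sc$channels, det)$R)
  }, 1)
  fit6 <- fit_calibration_line(attr(series6, "pH"), r6)
  expect_lt(fit6$se["slope"], fit1$se["slope"])
})

test_that("colocalization statistics behave on identity, permutation and inversion", {
  set.seed(42)
  a <- matrix(stats::rgamma(120 * 120, shape = 2), 120, 120)
  same <- colocalize(a, a)
  expect_equal(same$pearson_r, 1.0, tolerance = 1e-12)
  expect_equal(same$overlap_fraction, 0.2, tolerance = 0.01)
  perm <- matrix(sample(a), 120, 120)
  expect_lt(abs(colocalize(a, perm)$pearson_r), 0.05)
  inv <- -a + max(a)
  expect_equal(colocalize(a, inv)$pearson_r, -1.0, tolerance = 1e-12)
  expect_error(colocalize(a, a, mask = matrix(FALSE, 120, 120)), "empty mask")
})

test_that("group comparison reports means, SEMs and t-tests", {
  g <- list(a = c(6.1, 6.3, 6.2), b = c(6.1, 6.3, 6.2))
  res <- compare_vesicular_ph(g)
  expect_equal(res$tests$p, 1)
  expect_equal(res$tests$t, 0)
  set.seed(1)
  x <- rnorm(10, 0, 1); y <- rnorm(10, 10, 1)   # 10 SD offset
  res2 <- compare_vesicular_ph(list(a = x, b = y))
  expect_lt(res2$tests$p, 1e-6)
  expect_true(res2$tests$significant)
  expect_error(compare_vesicular_ph(list(a = 1, b = c(1, 2))), ">= 2 cells")
})
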