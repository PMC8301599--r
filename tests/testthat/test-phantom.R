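test_that("radius waveform hits end-diastole and peak systole exactly and is bounded", {
  expect_equal(radius_waveform(0, 2.0, 0.25), 2.0)
  expect_equal(radius_waveform(0.35, 2.0, 0.25, ps_phase = 0.35), 1.5)
  # brute-force search over a dense phase grid: the minimum is r_ed*(1 - c)
  g <- seq(0, 1, length.out = 1e5)
  expect_equal(min(radius_waveform(g, 2.0, 0.25)), 2.0 * 0.75, tolerance = 1e-9)
  expect_error(radius_waveform(0.2, 2.0, 1.0), "contraction")
  expect_error(radius_waveform(0.2, 2.0, -0.1), "contraction")
})

test_that("waveform is C1 across the cycle wrap and peak systole", {
  eps <- 1e-6
  d_left <- (radius_waveform(1 - eps, 2, .25) - radius_waveform(1 - 2 * eps, 2, .25)) / eps
  d_right <- (radius_waveform(eps, 2, .25) - radius_waveform(0, 2, .25)) / eps
  expect_lt(abs(d_left - d_right), 1e-4)
})

test_that("rendered short-axis images place the endocardial edge on the ground truth", {
  sp <- 6.4 / 128
  img <- render_short_axis(rep(1.4, 72), rep(2.2, 72),
                           image_size = 128, pixel_spacing = sp)
  edge <- edge_along_ray_mm(img, sp)
  expect_lt(abs(edge - 1.4), sp) # within one pixel
  # non-circular contour: edge along +y should track the radius at 90 degrees
  ang <- seq(0, 355, by = 5)
  r_endo <- 1.4 + 0.3 * cos(2 * ang * pi / 180)
  img2 <- render_short_axis(r_endo, r_endo + 0.8, ang,
                            image_size = 128, pixel_spacing = sp)
  expect_lt(abs(edge_along_ray_mm(img2, sp) - (1.4 - 0.3)), sp)
})

test_that("rendering is bit-identical under a fixed seed and the shadow darkens its sector", {
  a <- render_short_axis(rep(1.4, 36), rep(2.2, 36), image_size = 64,
                         pixel_spacing = 0.1, speckle_scale = 0.4, seed = 11)
  b <- render_short_axis(rep(1.4, 36), rep(2.2, 36), image_size = 64,
                         pixel_spacing = 0.1, speckle_scale = 0.4, seed = 11)
  expect_identical(a, b)
  sh <- list(enabled = TRUE, center_deg = 225, extent_deg = 60, attenuation = 0.4)
  noshadow <- render_short_axis(rep(1.4, 36), rep(2.2, 36), image_size = 64,
                                pixel_spacing = 0.1)
  shadow <- render_short_axis(rep(1.4, 36), rep(2.2, 36), image_size = 64,
                              pixel_spacing = 0.1, shadow = sh)
  n <- 64; cx <- (n + 1) / 2
  x <- matrix((seq_len(n) - cx) * 0.1, n, n, byrow = TRUE)
  y <- matrix((cx - seq_len(n)) * 0.1, n, n)
  th <- (atan2(y, x) * 180 / pi) %% 360
  sect <- abs(((th - 225 + 180) %% 360) - 180) <= 30
  expect_lt(mean(shadow[sect]), mean(noshadow[sect]))
  expect_equal(shadow[!sect], noshadow[!sect])
  expect_error(render_short_axis(rep(2.2, 36), rep(1.4, 36)), "epicardial")
})

test_that("cohort generation is reproducible, correctly sized, and geometrically valid", {
  cfg <- tiny_phantom_config(3, seed = 42)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_equal(nrow(co1), 3)
  expect_equal(length(unique(co1$animal_id)), 3)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$dataset[[2]]$intensities, co2$dataset[[2]]$intensities)
  # epi > endo at every anchor site and frame
  tr <- cohort_truth(co1)
  w <- tidyr::pivot_wider(
    tr[, c("animal_id", "frame", "theta_deg", "z_frac", "boundary", "radius_mm")],
    names_from = "boundary", values_from = "radius_mm")
  expect_true(all(w$epi > w$endo))
  # all radii positive, phase 0 first
  expect_true(all(tr$radius_mm > 0))
  expect_true(all(tr$phase[tr$frame == 1] == 0))
})

test_that("degenerate config collapses all animals onto one ground truth", {
  cfg <- tiny_phantom_config(3, seed = 7, endo_radius_sd = 0,
                             regional_amplitude_sd = 0)
  co <- generate_cohort(cfg, render_images = FALSE)
  expect_identical(co$truth[[1]]$radius_mm, co$truth[[2]]$radius_mm)
  expect_identical(co$truth[[1]]$radius_mm, co$truth[[3]]$radius_mm)
  # end-diastolic basal endocardial radius equals the configured value exactly
  t1 <- co$truth[[1]]
  expect_equal(
    unique(t1$radius_mm[t1$frame == 1 & t1$boundary == "endo" & t1$z_frac == 1]),
    1.5)
})

test_that("per-animal end-diastolic radii follow the configured distribution", {
  cfg <- tiny_phantom_config(200, seed = 9, endo_radius_ed = 1.5,
                             endo_radius_sd = 0.2)
  co <- generate_cohort(cfg, render_images = FALSE)
  r_ed <- vapply(co$truth, function(tr) {
    tr$radius_mm[tr$frame == 1 & tr$boundary == "endo" &
                   tr$z_frac == 1 & tr$theta_deg == 30]
  }, numeric(1))
  expect_lt(abs(sd(r_ed) - 0.2) / 0.2, 0.15)
  expect_lt(abs(mean(r_ed) - 1.5), 0.05)
})

test_that("phantom config rejects invalid geometry and timing", {
  expect_error(tiny_phantom_config(1, contraction_fraction = 1.2), "contraction")
  expect_error(tiny_phantom_config(1, frames_per_cycle = 4), "frames_per_cycle")
  expect_error(phantom_config(1, image_size = 32, pixel_spacing = 0.05),
               "field of view")
})

test_that("linear-family cohorts expose their latent structure", {
  co <- generate_linear_cohort(6, frames_per_cycle = 10, image_size = 10, seed = 2)
  expect_equal(nrow(co), 6)
  tr <- cohort_truth(co)
  expect_true(all(tr$radius_mm > 0))
  # noiseless images are exactly rank k_true after centering (the size
  # offset moves within the span of the latent patterns)
  f <- cohort_features(co)
  Xc <- sweep(f$combined, 2, colMeans(f$combined))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  expect_lt(sv[4] / sv[1], 1e-8)
})
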