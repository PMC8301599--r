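test_that("the 6:1:1 partition has exact sizes, disjoint whole-animal splits", {
  ids <- sprintf("a%03d", 1:136)
  p <- mc_partition(ids, seed = 1)
  expect_equal(c(length(p$train), length(p$val), length(p$test)), c(102, 17, 17))
  p16 <- mc_partition(sprintf("a%02d", 1:16), seed = 2)
  expect_equal(c(length(p16$train), length(p16$val), length(p16$test)), c(12, 2, 2))
  # determinism and variation
  expect_identical(mc_partition(ids, seed = 5), mc_partition(ids, seed = 5))
  expect_false(identical(mc_partition(ids, seed = 5), mc_partition(ids, seed = 6)))
  # disjointness and coverage over many seeds
  for (s in 1:10) {
    p <- mc_partition(ids, seed = s)
    expect_length(intersect(p$train, p$val), 0)
    expect_length(intersect(p$train, p$test), 0)
    expect_length(intersect(p$val, p$test), 0)
    expect_setequal(c(p$train, p$val, p$test), ids)
  }
  expect_error(mc_partition(sprintf("a%d", 1:7), 1), "at least 8")
})

test_that("paired t statistics match the closed form and a CDF oracle", {
  r <- paired_error_ttest(c(0, 2, 4), c(1, 2, 3)) # differences -1, 0, 1
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- paired_error_ttest(c(2, 4, 6), c(1, 2, 3)) # differences 1, 2, 3
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-12) # = 3.464...
  expect_equal(r2$t, 3.464, tolerance = 1e-3)
  expect_equal(r2$p, 2 * stats::pt(-abs(r2$t), df = 2), tolerance = 1e-10)
  # degenerate zero-variance differences
  rz <- paired_error_ttest(c(1, 1, 1), c(2, 2, 2))
  expect_true(rz$degenerate)
  expect_equal(rz$p, 0)
  rz0 <- paired_error_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rz0$p, 1)
  expect_error(paired_error_ttest(1:2, 1:2), "at least 3")
  expect_error(paired_error_ttest(1:3, 1:4), "equal length")
})

test_that("cross-validation recovers a noiseless model-family cohort almost perfectly", {
  co <- generate_linear_cohort(10, frames_per_cycle = 12, image_size = 12, seed = 31)
  cv <- run_cross_validation(co, variants = 2, n_iter = 4, k_grid = 3, seed = 7)
  expect_gt(min(cv$summary$median_r2), 0.99)
  expect_lt(max(cv$summary$median_mse), 1e-6)
  # splits are disjoint and cover the cohort on every iteration
  sp <- cv$splits |> dplyr::count(iteration, animal_id)
  expect_true(all(sp$n == 1))
  expect_equal(nrow(cv$splits), 4 * 10)
})

test_that("pure-noise images score near zero R^2 against the test-mean baseline", {
  co <- generate_linear_cohort(12, frames_per_cycle = 10, image_size = 10,
                               size_sd = 0, image_signal = "noise",
                               radius_signal = "none", radius_noise_sd = 0.1,
                               seed = 41)
  cv <- run_cross_validation(co, variants = 2, n_iter = 8, k_grid = 2, seed = 3)
  med_r2 <- median(cv$anchors$r2)
  expect_lt(abs(med_r2), 0.25) # no signal: R^2 ~ 0 up to Monte Carlo error
  expect_lt(med_r2, 0.1)
})

test_that("a single-value k grid bypasses selection and reproduces a direct fit", {
  co <- generate_linear_cohort(10, frames_per_cycle = 10, image_size = 10,
                               pixel_noise_sd = 0.02, radius_noise_sd = 0.02,
                               seed = 51)
  cv <- run_cross_validation(co, variants = 2, n_iter = 2, k_grid = 3, seed = 9)
  expect_true(all(cv$selected_k$k == 3))
  # direct fit on the same split gives the same test MSE
  part <- mc_partition(co$animal_id, seed = 9 + 1)
  train <- co[co$animal_id %in% part$train, ]
  m <- fit_boundary_model(train, 2, k = 3)
  test_ids <- part$test
  direct <- purrr::map_dfr(test_ids, function(a) {
    i <- match(a, co$animal_id)
    pr <- predict_radii(m, co$dataset[[i]])
    dplyr::mutate(pr, truth = co$truth[[i]]$radius_mm)
  }) |>
    dplyr::group_by(anchor_id) |>
    dplyr::summarise(mse = mean((radius_mm - truth)^2))
  cvm <- cv$anchors[cv$anchors$iteration == 1, ]
  expect_equal(cvm$mse[match(direct$anchor_id, cvm$anchor_id)], direct$mse,
               tolerance = 1e-10)
})

test_that("oversized k values are skipped with a warning", {
  co <- generate_linear_cohort(8, frames_per_cycle = 10, image_size = 8, seed = 61)
  expect_warning(
    cv <- run_cross_validation(co, variants = 2, n_iter = 1,
                               k_grid = c(2, 500), seed = 2),
    "skipped")
  expect_equal(unique(cv$selected_k$k), 2)
})

test_that("metric-table comparison flags exactly the shifted metric", {
  mesh <- build_lv_mesh(tube_radii(2, 2.5, 10), 0, 6, 0.12)
  base <- metric_table(mesh)
  set.seed(5)
  mk <- function(id, shift_ef = 0) {
    dplyr::mutate(base,
                  value = value + rnorm(nrow(base), 0, 0.01) +
                    ifelse(metric == "ef", shift_ef, 0),
                  id = id)
  }
  truth <- purrr::map_dfr(1:50, ~ mk(.x))
  same <- dplyr::mutate(truth, value = value) # identical copy
  cmp0 <- compare_metric_tables(truth, same)
  expect_equal(sum(cmp0$flagged), 0)
  # shift one metric by ~10 SDs of its paired noise
  pred <- purrr::map_dfr(1:50, ~ mk(.x, shift_ef = 0.2))
  pred$value <- pred$value + rnorm(nrow(pred), 0, 0.005)
  cmp1 <- compare_metric_tables(truth, pred)
  expect_equal(cmp1$metric[cmp1$flagged], "ef")
  expect_equal(sum(cmp1$flagged), 1)
  # Bonferroni bound: adjusted p in [p, 1]
  expect_true(all(cmp1$p_adjusted >= cmp1$p - 1e-15))
  expect_true(all(cmp1$p_adjusted <= 1))
  expect_error(compare_metric_tables(truth, pred[pred$id != 3, ]), "different datasets")
})

test_that("cv results expose tidy/glance views and a heatmap plot", {
  co <- generate_linear_cohort(9, frames_per_cycle = 10, image_size = 10,
                               pixel_noise_sd = 0.05, radius_noise_sd = 0.05,
                               seed = 71)
  cv <- run_cross_validation(co, variants = c(2, 3), n_iter = 2, k_grid = 3, seed = 11)
  expect_equal(nrow(tidy(cv)), 2 * 2 * 48)
  expect_true(all(c("variant", "boundary", "mean_mse") %in% names(glance(cv))))
  expect_equal(nrow(cv$heatmap), 2 * 2 * 24)
  expect_s3_class(autoplot(cv), "ggplot")
  # percent-significant table covers both boundaries and the one comparison
  expect_equal(nrow(cv$percent_significant), 2)
  expect_true(all(cv$percent_significant$pct_significant >= 0 &
                    cv$percent_significant$pct_significant <= 100))
})
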