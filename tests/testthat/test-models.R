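test_that("design assembly has the contracted shape for each variant", {
  tb <- time_basis(8)
  sc <- matrix(rnorm(20 * 3), 20, 3)
  ph <- rep(seq(0, 0.9, by = 0.1), 2)
  X1 <- assemble_design(sc, ph, tb, variant = 1)
  expect_equal(ncol(X1), 11) # k = 3 scores + 8 spline columns
  X2 <- assemble_design(sc, ph, tb, variant = 2)
  assist <- rep(c(1.5, 2.0), each = 10) # two animals' t=0 annotations
  X3 <- assemble_design(sc, ph, tb, variant = 3, assist_values = assist)
  expect_equal(ncol(X3), ncol(X2) + 1) # exactly one extra scalar column
  expect_equal(unique(X3[1:10, ncol(X3)]), 1.5)
  expect_equal(unique(X3[11:20, ncol(X3)]), 2.0)
  expect_error(assemble_design(sc, ph, tb, variant = 3), "assist")
})

test_that("least-squares fits match the normal-equations oracle", {
  set.seed(8)
  X <- cbind(matrix(rnorm(20 * 2), 20, 2),
             evaluate_time_basis(runif(20), time_basis(6)))
  y <- rnorm(20)
  beta_hat <- lvkin:::.lstsq(X, y)
  beta_oracle <- solve(crossprod(X), crossprod(X, y))
  expect_equal(as.numeric(beta_hat), as.numeric(beta_oracle), tolerance = 1e-8)
})

test_that("known regression coefficients are recovered from constructed data", {
  set.seed(9)
  tb <- time_basis(8)
  n <- 60
  ph <- runif(n)
  sc <- matrix(rnorm(n * 3), n, 3)
  gam <- rnorm(8, 0, 0.1)
  y <- 0.5 * sc[, 1] + evaluate_time_basis(ph, tb) %*% gam
  X <- assemble_design(sc, ph, tb, variant = 2)
  b <- lvkin:::.lstsq(X, y)
  expect_equal(b[1], 0.5, tolerance = 1e-8)
  expect_lt(sum((y - X %*% b)^2), 1e-16)
})

test_that("constant radii with zero image signal predict the constant at any phase", {
  tb <- time_basis(8)
  n <- 40
  ph <- seq(0, 1 - 1 / n, length.out = n)
  sc <- matrix(0, n, 2)
  y <- rep(1.7, n)
  X <- assemble_design(sc, ph, tb, variant = 2)
  b <- lvkin:::.lstsq(X, y)
  Xnew <- assemble_design(matrix(0, 5, 2), c(0.05, 0.21, 0.5, 0.77, 0.93), tb, 2)
  expect_equal(as.numeric(Xnew %*% b), rep(1.7, 5), tolerance = 1e-8)
})

test_that("a noiseless model-family cohort is fit essentially exactly", {
  co <- generate_linear_cohort(10, frames_per_cycle = 12, image_size = 12, seed = 13)
  train <- co[1:8, ]; test <- co[9:10, ]
  m <- fit_boundary_model(train, 2, k = 3)
  err <- vapply(9:10, function(i) {
    pr <- predict_radii(m, co$dataset[[i]])
    mean((pr$radius_mm - co$truth[[i]]$radius_mm)^2)
  }, numeric(1))
  expect_lt(max(err), 1e-6) # parameter recovery on held-out animals
  # predicting on a training dataset reproduces the fitted values
  feats <- cohort_features(train)
  mf <- lvkin:::build_model_frame(feats, m$image_bases, m$k)
  X <- cbind(mf$scores_combined, evaluate_time_basis(mf$phases, m$tbasis))
  fitted <- X %*% m$coefficients
  pr1 <- predict_radii(m, train$dataset[[1]])
  nt <- length(train$dataset[[1]]$cycle_phase)
  expect_equal(pr1$radius_mm, as.numeric(t(fitted[seq_len(nt), ])),
               tolerance = 1e-10)
})

test_that("predictions ignore basis components beyond the model's k", {
  co <- generate_linear_cohort(8, frames_per_cycle = 10, image_size = 10,
                               pixel_noise_sd = 0.02, seed = 21)
  feats <- cohort_features(co)
  bases_full <- fit_cohort_bases(feats, k_max = 6, scope = "combined")
  bases_trim <- list(bases_full[[1]])
  bases_trim[[1]]$components <- bases_full[[1]]$components[, 1:3, drop = FALSE]
  bases_trim[[1]]$sdev <- bases_full[[1]]$sdev[1:3]
  bases_trim[[1]]$k <- 3L
  m_full <- fit_boundary_model(co, 2, k = 3, image_bases = bases_full)
  m_trim <- fit_boundary_model(co, 2, k = 3, image_bases = bases_trim)
  p_full <- predict_radii(m_full, co$dataset[[1]])
  p_trim <- predict_radii(m_trim, co$dataset[[1]])
  expect_equal(p_full$radius_mm, p_trim$radius_mm, tolerance = 1e-10)
})

test_that("the assist annotation resolves per-animal size offsets that images cannot", {
  co <- generate_linear_cohort(12, frames_per_cycle = 12, image_size = 10,
                               size_sd = 0.3, image_signal = "noise", seed = 17)
  train <- co[1:9, ]; test <- co[10:12, ]
  m2 <- fit_boundary_model(train, 2, k = 3)
  m3 <- fit_boundary_model(train, 3, k = 3,
                           image_bases = m2$image_bases)
  grid <- anchor_grid()
  mse <- function(m) {
    mean(vapply(10:12, function(i) {
      tr <- co$truth[[i]]
      assist <- tr$radius_mm[tr$anchor_id == "endo_z050_th090" & tr$frame == 1]
      pr <- predict_radii(m, co$dataset[[i]],
                          assist_value = if (m$variant == 3) assist else NULL)
      mean((pr$radius_mm - tr$radius_mm)^2)
    }, numeric(1)))
  }
  expect_lt(mse(m3), mse(m2))
})

test_that("variant 3 refuses to run without its annotation", {
  co <- generate_linear_cohort(8, frames_per_cycle = 10, image_size = 8, seed = 2)
  m3 <- fit_boundary_model(co, 3, k = 2)
  expect_error(predict_radii(m3, co$dataset[[1]]), "assist")
})

test_that("tidy and glance expose coefficients and fit summary", {
  co <- generate_linear_cohort(8, frames_per_cycle = 10, image_size = 8, seed = 4)
  m <- fit_boundary_model(co, 2, k = 2, tbasis = time_basis(6))
  td <- tidy(m)
  expect_equal(nrow(td), 48 * (2 + 6))
  expect_true(all(c("anchor_id", "term", "estimate", "theta_deg") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$variant, 2)
  expect_equal(gl$n_anchors, 48)
})
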