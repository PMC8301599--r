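# Minimum-norm least squares via SVD: works for rank-deficient and
# underdetermined designs (k_max may approach the sample size in small
# permutations). Y may have multiple response columns.
.lstsq <- function(X, Y) {
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(X), ncol(as.matrix(Y))))
  Y <- as.matrix(Y)
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos])
}

#' Assemble the per-anchor regression design
#'
#' Builds the design matrix of the boundary-prediction models: image
#' principal-component scores alongside the evaluated time basis, plus —
#' for the assisted variant 3 — a single column repeating each animal's
#' true assist-anchor radius at its first frame (end-diastole) across all
#' of that animal's rows. No intercept column is added: the periodic
#' B-spline basis spans constants.
#'
#' @param scores Score matrix (`n_obs` x `k`), one row per (animal, frame)
#'   observation.
#' @param phases Cycle phase per observation.
#' @param tbasis A [time_basis()].
#' @param variant 1, 2 or 3. Variants differ upstream in which scores are
#'   supplied (per-slice for 1, combined for 2-3); here variant 3
#'   additionally requires `assist_values`.
#' @param assist_values For variant 3: the assist radius per observation
#'   (already expanded to rows, constant within an animal).
#' @return The design matrix with named columns.
#' @export
assemble_design <- function(scores, phases, tbasis, variant,
                            assist_values = NULL) {
  scores <- as.matrix(scores)
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  X <- cbind(scores, evaluate_time_basis(phases, tbasis))
  if (variant == 3) {
    if (is.null(assist_values)) {
      abort("variant 3 requires assist_values (the t = 0 annotation)")
    }
    X <- cbind(X, assist = assist_values)
  }
  X
}

#' Fit a boundary-prediction model
#'
#' Fits one of the three model variants by least squares, independently
#' for each of the 48 anchor points. All variants regress an anchor's
#' radius on image principal-component scores plus a periodic B-spline
#' basis over cycle phase. Variant 1 uses scores of the anchor's own
#' short-axis slice (four per-slice PCA bases); variant 2 uses one PCA of
#' the four slices concatenated; variant 3 adds a single scalar times the
#' user-annotated end-diastolic radius of one assist anchor.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]) restricted to
#'   the training animals.
#' @param variant 1, 2 or 3.
#' @param k Number of principal components.
#' @param tbasis A [time_basis()].
#' @param image_bases Optional pre-fitted bases (as returned in the
#'   `image_bases` field); refit from `cohort` when `NULL`.
#' @param assist_anchor Anchor id string for variant 3; default the
#'   endocardial anterior mid-ventricle point (theta = 90, z = 0.5).
#' @return An object of class `boundary_model`.
#' @export
fit_boundary_model <- function(cohort, variant, k, tbasis = time_basis(),
                               image_bases = NULL,
                               assist_anchor = "endo_z050_th090") {
  stopifnot(variant %in% 1:3)
  feats <- cohort_features(cohort)
  if (is.null(image_bases)) {
    image_bases <- fit_cohort_bases(feats, k_max = k,
                                    scope = if (variant == 1) "per-slice" else "combined")
  }
  mf <- build_model_frame(feats, image_bases, k)
  .fit_from_frame(mf, variant, k, tbasis, image_bases, assist_anchor)
}

.fit_from_frame <- function(mf, variant, k, tbasis, image_bases, assist_anchor) {
  grid <- anchor_grid()
  n_obs <- length(mf$phases)
  avail <- if (variant == 1) {
    min(vapply(mf$scores_slice, ncol, 1L))
  } else {
    ncol(mf$scores_combined)
  }
  if (k > avail) {
    warn(sprintf("k = %d exceeds the fitted basis rank %d; clipped", k, avail))
    k <- avail
  }
  Phi <- evaluate_time_basis(mf$phases, tbasis)
  coefs <- matrix(NA_real_, k + tbasis$n_basis + (variant == 3), 48)
  train_sse <- numeric(48)
  assist_values <- NULL
  if (variant == 3) {
    ai <- match(assist_anchor, grid$anchor_id)
    if (is.na(ai)) abort(sprintf("unknown assist anchor '%s'", assist_anchor))
    assist_values <- .assist_per_row(mf, ai)
  }
  for (j in seq_len(48)) {
    W <- if (variant == 1) {
      zi <- match(grid$z_frac[j], ANCHOR_ZFRACS)
      mf$scores_slice[[zi]][, seq_len(k), drop = FALSE]
    } else {
      mf$scores_combined[, seq_len(k), drop = FALSE]
    }
    X <- cbind(W, Phi)
    if (variant == 3) X <- cbind(X, assist_values)
    if (nrow(X) <= ncol(X)) {
      warn(sprintf("anchor %s: %d rows for %d columns; minimum-norm fit",
                   grid$anchor_id[j], nrow(X), ncol(X)))
    }
    y <- mf$radii[, j]
    b <- .lstsq(X, y)
    coefs[, j] <- b
    train_sse[j] <- sum((y - X %*% b)^2)
  }
  colnames(coefs) <- grid$anchor_id
  rownames(coefs) <- c(sprintf("PC%d", seq_len(k)),
                       sprintf("S%d", seq_len(tbasis$n_basis)),
                       if (variant == 3) "assist")
  structure(list(
    variant = variant, k = k, tbasis = tbasis, image_bases = image_bases,
    coefficients = coefs, assist_anchor = if (variant == 3) assist_anchor else NULL,
    anchor_grid = grid, n_train_rows = n_obs,
    train_mse = sum(train_sse) / (48 * n_obs)
  ), class = "boundary_model")
}

#' @export
print.boundary_model <- function(x, ...) {
  cat(sprintf("<boundary_model> variant %d, k = %d, %d spline bases, 48 anchors (train MSE %.2e mm^2)\n",
              x$variant, x$k, x$tbasis$n_basis, x$train_mse))
  invisible(x)
}

#' Predict anchor radii for a dataset
#'
#' Applies a fitted [fit_boundary_model()] to one cine dataset: extracts
#' the four standard slices at every frame, projects them with the
#' model's stored image basis, evaluates the time basis at the dataset's
#' cycle phases, and returns the 48 predicted radii per frame. The
#' assisted variant requires this dataset's true end-diastolic radius at
#' the assist anchor.
#'
#' @param model A `boundary_model`.
#' @param dataset A [cine_dataset()].
#' @param assist_value For variant 3: the true assist-anchor radius (mm)
#'   at the dataset's first frame.
#' @return A tibble of predicted anchor radii (`frame`, `phase`,
#'   `theta_deg`, `boundary`, `z_frac`, `radius_mm`, `anchor_id`).
#' @export
predict_radii <- function(model, dataset, assist_value = NULL) {
  stopifnot(inherits(model, "boundary_model"), inherits(dataset, "cine_dataset"))
  if (model$variant == 3 && is.null(assist_value)) {
    abort("variant 3 requires the end-diastolic assist_value annotation")
  }
  feats <- dataset_features(dataset)
  nt <- length(dataset$cycle_phase)
  Phi <- evaluate_time_basis(dataset$cycle_phase, model$tbasis)
  grid <- model$anchor_grid
  k <- model$k
  if (model$variant == 1) {
    scores <- lapply(1:4, function(zi) {
      project_images(feats$slices[[zi]], model$image_bases[[zi]], k)
    })
  } else {
    scores <- project_images(feats$combined, model$image_bases[[1]], k)
  }
  pred <- matrix(NA_real_, nt, 48)
  for (j in seq_len(48)) {
    W <- if (model$variant == 1) {
      scores[[match(grid$z_frac[j], ANCHOR_ZFRACS)]]
    } else scores
    X <- cbind(W, Phi)
    if (model$variant == 3) X <- cbind(X, rep(assist_value, nt))
    pred[, j] <- X %*% model$coefficients[, j]
  }
  tidyr::expand_grid(frame = seq_len(nt), grid) |>
    dplyr::mutate(
      phase = dataset$cycle_phase[.data$frame],
      radius_mm = pred[cbind(.data$frame, rep(seq_len(48), nt))]
    ) |>
    dplyr::select("frame", "phase", "theta_deg", "boundary", "z_frac",
                  "radius_mm", "anchor_id")
}

# ---- feature plumbing shared by fitting and cross-validation --------------

#' Extract modeling features from one dataset
#'
#' Pulls the four standard slices at every frame and returns both the
#' per-slice and concatenated (combined) vectorized pixel matrices.
#'
#' @param dataset A [cine_dataset()].
#' @return List with `slices` (list of 4 matrices, `n_frames` x pixels),
#'   `combined` (`n_frames` x 4*pixels), `phases`, `animal_id`.
#' @export
dataset_features <- function(dataset) {
  nt <- length(dataset$cycle_phase)
  per_slice <- lapply(1:4, function(i) NULL)
  rows <- vector("list", nt)
  for (ti in seq_len(nt)) {
    sl <- extract_slices(dataset, ti)
    rows[[ti]] <- lapply(sl, vectorize_image)
  }
  slices <- lapply(1:4, function(si) {
    do.call(rbind, lapply(rows, `[[`, si))
  })
  list(slices = slices, combined = do.call(cbind, slices),
       phases = dataset$cycle_phase, animal_id = dataset$animal_id)
}

#' Extract modeling features for a whole cohort
#'
#' @param cohort A cohort tibble with `dataset` and `truth` list-columns.
#' @return List with per-observation (animal, frame) feature blocks:
#'   `slices` (4 matrices), `combined`, `phases`, `animal`, `radii`
#'   (`n_obs` x 48 ground-truth matrix, columns in [anchor_grid()] order).
#' @export
cohort_features <- function(cohort) {
  grid <- anchor_grid()
  per <- purrr::map(seq_len(nrow(cohort)), function(i) {
    f <- dataset_features(cohort$dataset[[i]])
    tr <- cohort$truth[[i]]
    nt <- length(f$phases)
    R <- matrix(NA_real_, nt, 48)
    idx <- match(tr$anchor_id, grid$anchor_id)
    R[cbind(tr$frame, idx)] <- tr$radius_mm
    list(f = f, R = R)
  })
  list(
    slices = lapply(1:4, function(si) {
      do.call(rbind, purrr::map(per, ~ .x$f$slices[[si]]))
    }),
    combined = do.call(rbind, purrr::map(per, ~ .x$f$combined)),
    phases = unlist(purrr::map(per, ~ .x$f$phases)),
    animal = rep(cohort$animal_id,
                 purrr::map_int(per, ~ length(.x$f$phases))),
    radii = do.call(rbind, purrr::map(per, ~ .x$R))
  )
}

#' Fit the PCA bases a model scope needs from cohort features
#'
#' @param feats Result of [cohort_features()] (training animals only).
#' @param k_max Components to retain.
#' @param scope `"per-slice"` (four bases) or `"combined"` (one basis).
#' @return A list of `image_basis` objects (length 4 or 1).
#' @export
fit_cohort_bases <- function(feats, k_max, scope) {
  if (scope == "per-slice") {
    lapply(1:4, function(si) fit_image_basis(feats$slices[[si]], k_max, "per-slice"))
  } else {
    list(fit_image_basis(feats$combined, k_max, "combined"))
  }
}

# Project cohort features onto fitted bases at k_max; fitting at smaller k
# just subsets score columns.
build_model_frame <- function(feats, image_bases, k_max) {
  if (length(image_bases) == 4) {
    scores_slice <- lapply(1:4, function(si) {
      project_images(feats$slices[[si]], image_bases[[si]],
                     min(k_max, image_bases[[si]]$k))
    })
    scores_combined <- NULL
  } else {
    scores_slice <- NULL
    scores_combined <- project_images(feats$combined, image_bases[[1]],
                                      min(k_max, image_bases[[1]]$k))
  }
  list(scores_slice = scores_slice, scores_combined = scores_combined,
       phases = feats$phases, animal = feats$animal, radii = feats$radii)
}

# assist value per observation row: each animal's true assist-anchor radius
# at its first frame, repeated across that animal's rows
.assist_per_row <- function(mf, anchor_index) {
  ids <- unique(mf$animal)
  vals <- vapply(ids, function(a) {
    rows <- which(mf$animal == a)
    mf$radii[rows[1], anchor_index]
  }, numeric(1))
  vals[match(mf$animal, ids)]
}

#' @describeIn fit_boundary_model Tidy per-anchor coefficients.
#' @param x A `boundary_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.boundary_model <- function(x, ...) {
  co <- x$coefficients
  tibble(
    anchor_id = rep(colnames(co), each = nrow(co)),
    term = rep(rownames(co), times = ncol(co)),
    estimate = as.numeric(co)
  ) |>
    dplyr::left_join(x$anchor_grid, by = "anchor_id") |>
    dplyr::select("anchor_id", "theta_deg", "boundary", "z_frac", "term", "estimate")
}

#' @describeIn fit_boundary_model One-row model summary.
#' @exportS3Method generics::glance
glance.boundary_model <- function(x, ...) {
  tibble(
    variant = x$variant, k = x$k, n_basis = x$tbasis$n_basis,
    n_anchors = ncol(x$coefficients), n_train_rows = x$n_train_rows,
    train_mse = x$train_mse
  )
}
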