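#' Fit a principal-component image basis
#'
#' Compresses short-axis images to a low-dimensional subspace: the
#' components are the leading eigenvectors of the training covariance,
#' ordered by decreasing explained variance, with the per-pixel training
#' mean removed. When pixels outnumber samples (the usual case for
#' ultrasound frames) the decomposition goes through the n x n Gram
#' matrix, which is algebraically identical to the covariance
#' eigendecomposition for the leading components.
#'
#' The mean and components depend only on the images supplied here; to
#' avoid leakage, cross-validation refits the basis on each permutation's
#' training images only.
#'
#' @param images Numeric matrix, one vectorized (row-major) image per row.
#'   For the combined scope, the four slices of each frame are
#'   concatenated into one row before calling.
#' @param k_max Number of components to retain; silently limited to
#'   `min(n_samples - 1, n_pixels)` with a warning if larger.
#' @param scope `"per-slice"` or `"combined"`; recorded metadata only.
#' @return An object of class `image_basis` with fields `mean` (length-p),
#'   `components` (p x k, orthonormal columns), `sdev`, `k`, `scope`, `p`.
#' @export
fit_image_basis <- function(images, k_max, scope = c("per-slice", "combined")) {
  scope <- match.arg(scope)
  images <- as.matrix(images)
  n <- nrow(images); p <- ncol(images)
  if (n < 2) abort("need at least 2 training images")
  k_lim <- min(n - 1L, p)
  if (k_max > k_lim) {
    warn(sprintf("k_max = %d exceeds the data rank limit %d; clipped", k_max, k_lim))
    k_max <- k_lim
  }
  mu <- colMeans(images)
  Xc <- sweep(images, 2, mu)
  if (p > n) {
    G <- tcrossprod(Xc) # n x n
    eg <- eigen(G, symmetric = TRUE)
    pos <- which(eg$values > max(eg$values[1], 0) * 1e-12)
    k_eff <- min(k_max, length(pos))
    d2 <- eg$values[seq_len(k_eff)]
    V <- crossprod(Xc, eg$vectors[, seq_len(k_eff), drop = FALSE]) # p x k
    V <- sweep(V, 2, sqrt(d2), "/")
    sdev <- sqrt(d2 / (n - 1))
  } else {
    eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    k_eff <- min(k_max, sum(eg$values > max(eg$values[1], 0) * 1e-12))
    k_eff <- max(k_eff, 1L)
    V <- eg$vectors[, seq_len(k_eff), drop = FALSE]
    sdev <- sqrt(pmax(eg$values[seq_len(k_eff)], 0))
  }
  if (ncol(V) == 0) { # degenerate all-identical training set
    V <- matrix(0, p, 1)
    sdev <- 0
  }
  structure(list(mean = mu, components = V, sdev = sdev, k = ncol(V),
                 scope = scope, p = p),
            class = "image_basis")
}

#' @export
print.image_basis <- function(x, ...) {
  cat(sprintf("<image_basis> %d components over %d pixels (%s scope)\n",
              x$k, x$p, x$scope))
  invisible(x)
}

#' Project images onto an image basis
#'
#' @param images Matrix of vectorized images (rows), or a single image
#'   matrix/vector.
#' @param basis An [fit_image_basis()] result.
#' @param k Number of leading components to use (`<= basis$k`).
#' @return Score matrix, `n_samples` x `k`.
#' @export
project_images <- function(images, basis, k = basis$k) {
  stopifnot(inherits(basis, "image_basis"))
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  if (is.matrix(images) && ncol(images) != basis$p && length(images) == basis$p) {
    images <- matrix(as.numeric(t(images)), nrow = 1) # single row-major image
  }
  images <- as.matrix(images)
  if (ncol(images) != basis$p) {
    abort(sprintf("image length %d does not match basis dimension %d",
                  ncol(images), basis$p))
  }
  if (k > basis$k) abort(sprintf("k = %d exceeds fitted component count %d", k, basis$k))
  sweep(images, 2, basis$mean) %*% basis$components[, seq_len(k), drop = FALSE]
}

#' Vectorize an image matrix row-major
#'
#' Images are flattened row by row so that pixel order is independent of
#' R's column-major storage convention.
#'
#' @param img A 2D matrix.
#' @return Numeric vector of length `nrow * ncol`.
#' @export
vectorize_image <- function(img) as.numeric(t(img))

#' Time basis over the cardiac cycle
#'
#' A cubic B-spline basis on uniform knots over cycle phase `[0, 1)`. The
#' default periodic basis wraps so that every basis function (and its
#' first derivative) is continuous across the end-diastole wrap; rows of
#' the evaluated basis sum to 1 (partition of unity), so the basis spans
#' constants and no separate intercept is needed in the regression
#' models.
#'
#' @param n_basis Number of basis functions (>= 4 for cubic).
#' @param periodic Wrap the basis around the cycle (default `TRUE`).
#' @return An object of class `time_basis`.
#' @export
time_basis <- function(n_basis = 8, periodic = TRUE) {
  n_basis <- as.integer(n_basis)
  if (n_basis < 4) abort("cubic B-spline basis needs n_basis >= 4")
  structure(list(n_basis = n_basis, periodic = periodic,
                 knots = seq(0, 1, length.out = n_basis + 1)),
            class = "time_basis")
}

#' @export
print.time_basis <- function(x, ...) {
  cat(sprintf("<time_basis> %d cubic B-splines, %s\n", x$n_basis,
              if (x$periodic) "periodic" else "clamped"))
  invisible(x)
}

#' Evaluate the time basis at cycle phases
#'
#' @param phases Cycle fractions; values outside `[0, 1)` are wrapped
#'   modulo 1 (with a note).
#' @param basis A [time_basis()].
#' @return Matrix `length(phases)` x `n_basis`.
#' @export
evaluate_time_basis <- function(phases, basis) {
  stopifnot(inherits(basis, "time_basis"))
  if (any(phases < 0 | phases >= 1)) {
    inform("phases outside [0, 1) wrapped modulo 1")
    phases <- phases %% 1
  }
  nb <- basis$n_basis
  if (basis$periodic) {
    # cubic B-splines on extended uniform knots; wrap the three splines
    # whose support crosses the cycle boundary
    knots <- seq(-3, nb + 3) / nb
    D <- splines::splineDesign(knots, phases, ord = 4, outer.ok = TRUE)
    # D has nb + 3 columns; B_{j+nb} is B_j shifted by one period, so the
    # periodic basis folds columns nb+1..nb+3 onto columns 1..3
    P <- D[, 1:nb, drop = FALSE]
    P[, 1:3] <- P[, 1:3] + D[, (nb + 1):(nb + 3), drop = FALSE]
    colnames(P) <- sprintf("S%d", seq_len(nb))
    P
  } else {
    knots <- c(rep(0, 4), seq(0, 1, length.out = nb - 2)[-c(1, nb - 2)], rep(1, 4))
    D <- splines::splineDesign(knots, phases, ord = 4)
    colnames(D) <- sprintf("S%d", seq_len(nb))
    D
  }
}
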