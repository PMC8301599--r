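#' The standard 48-point anchor grid
#'
#' The left-ventricular wall is parameterized by 48 anchor points: 6
#' rotations about the long axis (30, 90, 150, 210, 270, 330 degrees
#' counterclockwise from the +x axis, septum on -x), 2 boundaries
#' (endocardium, epicardium), and 4 short-axis slices at 25, 50, 75 and
#' 100% of the apex-to-base distance. Each anchor's state at a time point
#' is its radial distance from the central z-axis.
#'
#' @return A tibble with 48 rows and columns `theta_deg`, `boundary`
#'   (`"endo"` or `"epi"`), `z_frac`, and a stable `anchor_id` string.
#'   Rows are ordered by `z_frac` ascending, then boundary (endo before
#'   epi), then `theta_deg` ascending.
#' @examples
#' anchor_grid()
#' @export
anchor_grid <- function() {
  g <- tidyr::expand_grid(
    z_frac = ANCHOR_ZFRACS,
    boundary = ANCHOR_BOUNDARIES,
    theta_deg = ANCHOR_THETAS
  )
  g <- dplyr::select(g, "theta_deg", "boundary", "z_frac")
  dplyr::mutate(
    g,
    anchor_id = sprintf("%s_z%03d_th%03d", .data$boundary,
                        as.integer(round(.data$z_frac * 100)),
                        as.integer(.data$theta_deg))
  )
}

#' Convert anchor radii to 3D coordinates
#'
#' Maps polar anchor descriptions to Cartesian points in the standard
#' frame: `x = r cos(theta)`, `y = r sin(theta)`, `z` linearly placed
#' between the apex and base positions at the relevant frame. The septal
#' wall lies on negative x (standard radiological orientation).
#'
#' @param radii A data frame with columns `theta_deg`, `z_frac`, and
#'   `radius_mm` (extra columns are preserved).
#' @param apex_z,base_z Axial positions of apex and base in mm for the
#'   frame(s) in question; recycled against rows of `radii`.
#' @return The input tibble with `x_mm`, `y_mm`, `z_mm` columns appended.
#' @export
anchors_to_points <- function(radii, apex_z, base_z) {
  stopifnot(all(c("theta_deg", "z_frac", "radius_mm") %in% names(radii)))
  th <- radii$theta_deg * pi / 180
  tibble::as_tibble(radii) |>
    dplyr::mutate(
      x_mm = .data$radius_mm * cos(th),
      y_mm = .data$radius_mm * sin(th),
      z_mm = apex_z + .data$z_frac * (base_z - apex_z)
    )
}

#' Recover polar anchor coordinates from Cartesian points
#'
#' Inverse of [anchors_to_points()] for the in-plane part: returns radius
#' and angle (degrees in `[0, 360)`) from `x_mm`, `y_mm` columns.
#'
#' @param points A data frame with `x_mm` and `y_mm` columns.
#' @return The input with `radius_mm` and `theta_deg` columns replaced or
#'   appended.
#' @export
points_to_anchors <- function(points) {
  tibble::as_tibble(points) |>
    dplyr::mutate(
      radius_mm = sqrt(.data$x_mm^2 + .data$y_mm^2),
      theta_deg = (atan2(.data$y_mm, .data$x_mm) * 180 / pi) %% 360
    )
}

#' Extract the four standard short-axis slices from a cine frame
#'
#' Interpolates image planes at 25, 50, 75 and 100% of the apex-to-base
#' distance for the requested frame, taking the apex/base axial positions
#' at that frame so that through-plane motion is compensated: a plane at a
#' fixed anatomical fraction is re-sampled from the stored z stack as the
#' heart shortens and lengthens. Interpolation between stored slices is
#' linear; a request on a stored plane returns that plane exactly.
#'
#' @param dataset A [cine_dataset()].
#' @param frame Frame index (1-based).
#' @param z_fracs Apex-to-base fractions to extract (default the four
#'   standard slices).
#' @return A list of 2D image matrices, one per requested fraction, named
#'   by fraction.
#' @export
extract_slices <- function(dataset, frame, z_fracs = ANCHOR_ZFRACS) {
  stopifnot(inherits(dataset, "cine_dataset"))
  nz <- length(dataset$slice_z)
  if (nz < 2) abort("dataset must store at least 2 z slices")
  apex <- dataset$apex_z[frame]
  base <- dataset$base_z[frame]
  if (!isTRUE(apex < base)) {
    abort(sprintf("apex_z must lie below base_z at frame %d", frame))
  }
  sz <- dataset$slice_z
  out <- lapply(z_fracs, function(f) {
    z <- apex + f * (base - apex)
    if (z < min(sz) - 1e-9 || z > max(sz) + 1e-9) {
      abort(sprintf(
        "requested plane z = %.3f mm at frame %d lies outside the stored stack [%.3f, %.3f]",
        z, frame, min(sz), max(sz)
      ))
    }
    z <- min(max(z, min(sz)), max(sz))
    i <- findInterval(z, sz, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nz - 1L)
    w <- (z - sz[i]) / (sz[i + 1] - sz[i])
    (1 - w) * dataset$intensities[frame, i, , ] +
      w * dataset$intensities[frame, i + 1, , ]
  })
  names(out) <- sprintf("z%03d", as.integer(round(z_fracs * 100)))
  out
}

#' Rigid transform specification
#'
#' Real acquisitions are manually reoriented to the standard frame (apex
#' and base on the z-axis, septum on -x); this package instead accepts a
#' user-supplied rigid transform applied to the voxel grid before slice
#' extraction. Phantom data are generated pre-aligned, so the default is
#' the identity.
#'
#' @param rotation Either a 3x3 rotation matrix or a length-3 numeric of
#'   intrinsic Euler angles in degrees (rotations about z, then y, then x).
#' @param translation Length-3 numeric translation in mm (x, y, z).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (is.numeric(rotation) && length(rotation) == 3 && !is.matrix(rotation)) {
    a <- rotation * pi / 180
    Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])), 3, byrow = TRUE)
    rotation <- Rz %*% Ry %*% Rx
  }
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("rotation must be orthonormal")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to a cine dataset
#'
#' Resamples every frame's volume under the inverse rigid map with
#' trilinear interpolation, so the returned dataset is expressed in the
#' standard frame. Voxels mapped from outside the original field of view
#' are filled with the volume's minimum intensity.
#'
#' @param dataset A [cine_dataset()].
#' @param transform A [rigid_transform()].
#' @return A new `cine_dataset` on the same voxel grid.
#' @export
apply_rigid_transform <- function(dataset, transform) {
  stopifnot(inherits(dataset, "cine_dataset"), inherits(transform, "rigid_transform"))
  if (max(abs(transform$rotation - diag(3))) < 1e-12 &&
      max(abs(transform$translation)) < 1e-12) {
    return(dataset)
  }
  d <- dim(dataset$intensities) # (t, z, y, x)
  n <- d[3]
  sp <- dataset$pixel_spacing
  # world coords of output voxels (image center = z-axis origin)
  xs <- (seq_len(d[4]) - (d[4] + 1) / 2) * sp
  ys <- ((d[3] + 1) / 2 - seq_len(d[3])) * sp
  zs <- dataset$slice_z
  grid <- expand.grid(y = ys, x = xs) # matches matrix [row=y, col=x] vectorization
  Rinv <- t(transform$rotation)
  out <- dataset$intensities
  for (ti in seq_len(d[1])) {
    for (zi in seq_len(d[2])) {
      pts <- cbind(grid$x, grid$y, zs[zi])
      src <- sweep(pts, 2, transform$translation) %*% t(Rinv)
      # back to fractional indices
      ci <- src[, 1] / sp + (d[4] + 1) / 2
      ri <- (d[3] + 1) / 2 - src[, 2] / sp
      zi_f <- approx(zs, seq_along(zs), xout = src[, 3], rule = 1)$y
      out[ti, zi, , ] <- .trilinear(dataset$intensities[ti, , , ], zi_f, ri, ci, d[2], d[3], d[4])
    }
  }
  dataset$intensities <- out
  dataset
}

# Trilinear sample of vol[z, y, x] at fractional indices; NA coords or
# out-of-range fall back to min(vol).
.trilinear <- function(vol, z, r, c, nz, nr, nc) {
  fill <- min(vol)
  ok <- !is.na(z) & z >= 1 & z <= nz & r >= 1 & r <= nr & c >= 1 & c <= nc
  res <- rep(fill, length(z))
  if (any(ok)) {
    z0 <- pmin(floor(z[ok]), nz - 1); wz <- z[ok] - z0
    r0 <- pmin(floor(r[ok]), nr - 1); wr <- r[ok] - r0
    c0 <- pmin(floor(c[ok]), nc - 1); wc <- c[ok] - c0
    idx <- function(zz, rr, cc) vol[cbind(zz, rr, cc)]
    res[ok] <-
      (1 - wz) * ((1 - wr) * ((1 - wc) * idx(z0, r0, c0) + wc * idx(z0, r0, c0 + 1)) +
                  wr * ((1 - wc) * idx(z0, r0 + 1, c0) + wc * idx(z0, r0 + 1, c0 + 1))) +
      wz * ((1 - wr) * ((1 - wc) * idx(z0 + 1, r0, c0) + wc * idx(z0 + 1, r0, c0 + 1)) +
            wr * ((1 - wc) * idx(z0 + 1, r0 + 1, c0) + wc * idx(z0 + 1, r0 + 1, c0 + 1)))
  }
  matrix(res, nr, nc)
}
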