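# Periodic spline evaluation on a closed 360-degree domain: radii given at
# `angles` (degrees, strictly increasing), evaluated at arbitrary angles.
.periodic_angle_spline <- function(angles, radii, at) {
  a0 <- angles[1]
  x <- c(angles, angles[1] + 360)
  y <- c(radii, radii[1])
  at_mapped <- ((at - a0) %% 360) + a0
  spline(x, y, method = "periodic", xout = at_mapped)$y
}

# Periodic spline over cycle phase [0, 1)
.periodic_phase_spline <- function(phases, values, at) {
  x <- c(phases, phases[1] + 1)
  y <- c(values, values[1])
  at_mapped <- ((at - phases[1]) %% 1) + phases[1]
  spline(x, y, method = "periodic", xout = at_mapped)$y
}

#' Interpolate a closed boundary contour from 6 anchor radii
#'
#' Produces a smooth closed curve through the six per-angle control radii
#' and evaluates its radius at the requested output angles. The default
#' engine is a periodic parametric cubic spline in polar form (radius as
#' a periodic function of angle), which interpolates the control points
#' and is C2-continuous across the 360-to-0 wrap. A Hobby-style
#' tension-based closed Bezier curve through the Cartesian control points
#' is available as an alternative engine behind the same interface; it
#' interpolates the control points and is C1, but reproduces a circle
#' only to cubic-Bezier arc accuracy rather than exactly.
#'
#' @param radii Radii (mm) at `input_angles`; all strictly positive.
#' @param output_angles Angles (degrees) to evaluate; default 60 uniform.
#' @param input_angles Angles of the control radii (default the standard
#'   6 rotations).
#' @param engine `"spline"` (default) or `"hobby"`.
#' @return Radii at `output_angles`.
#' @export
interpolate_closed_curve <- function(radii,
                                     output_angles = seq(0, 354, by = 6),
                                     input_angles = ANCHOR_THETAS,
                                     engine = c("spline", "hobby")) {
  engine <- match.arg(engine)
  if (any(radii <= 0)) abort("contour radii must be strictly positive")
  stopifnot(length(radii) == length(input_angles))
  if (engine == "spline") {
    .periodic_angle_spline(input_angles, radii, output_angles)
  } else {
    th <- input_angles * pi / 180
    pts <- cbind(radii * cos(th), radii * sin(th))
    poly <- hobby_closed_curve(pts, n_per_segment = 64)
    ang <- (atan2(poly[, 2], poly[, 1]) * 180 / pi) %% 360
    r <- sqrt(rowSums(poly^2))
    o <- order(ang)
    .interp_periodic(ang[o], r[o], output_angles)
  }
}

#' Closed Hobby curve through 2D control points
#'
#' Implements John Hobby's tension-1 interpolating curve for a closed
#' polygon: tangent directions at the control points are chosen by
#' solving the cyclic tridiagonal "mock curvature" system, and each
#' segment becomes a cubic Bezier with Hobby's velocity formula setting
#' the handle lengths. The result is C1-continuous and visually fair.
#'
#' @param points n x 2 matrix of control points (closed; do not repeat
#'   the first point).
#' @param n_per_segment Samples per Bezier segment in the returned
#'   polyline.
#' @return Matrix of curve samples (n * n_per_segment) x 2.
#' @export
hobby_closed_curve <- function(points, n_per_segment = 32) {
  z <- complex(real = points[, 1], imaginary = points[, 2])
  n <- length(z)
  stopifnot(n >= 3)
  succ <- c(2:n, 1); prev <- c(n, 1:(n - 1))
  chord <- z[succ] - z
  d <- Mod(chord)
  gamma <- Arg(chord)
  # turning angle at each point: direction change from incoming to outgoing chord
  psi <- gamma - gamma[prev]
  psi <- Arg(exp(1i * psi)) # wrap to (-pi, pi]
  # cyclic tridiagonal system for departure angles theta (rel. to chords):
  #   a_i theta_{i-1} + b_i theta_i + c_i theta_{i+1} = rhs_i
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in seq_len(n)) {
    ip <- prev[i]; is_ <- succ[i]
    A[i, ip] <- 1 / d[ip]
    A[i, i] <- 2 * (1 / d[ip] + 1 / d[i])
    A[i, is_] <- 1 / d[i]
    rhs[i] <- -(2 * psi[i] / d[ip] + psi[is_] / d[i])
  }
  theta <- solve(A, rhs)
  phi <- -psi[succ] - theta[succ] # arrival angle at segment end, rel. chord
  out <- vector("list", n)
  tseq <- seq(0, 1, length.out = n_per_segment + 1)[-(n_per_segment + 1)]
  for (i in seq_len(n)) {
    is_ <- succ[i]
    rho <- .hobby_velocity(theta[i], phi[i])
    sigma <- .hobby_velocity(phi[i], theta[i])
    c1 <- z[i] + rho * chord[i] * exp(1i * theta[i])
    c2 <- z[is_] - sigma * chord[i] * exp(-1i * phi[i])
    b <- (1 - tseq)^3 * z[i] + 3 * (1 - tseq)^2 * tseq * c1 +
      3 * (1 - tseq) * tseq^2 * c2 + tseq^3 * z[is_]
    out[[i]] <- b
  }
  b <- unlist(out)
  cbind(Re(b), Im(b))
}

# Hobby's velocity (handle length as a fraction of the chord), tension 1
.hobby_velocity <- function(theta, phi) {
  num <- 2 + sqrt(2) * (sin(theta) - sin(phi) / 16) *
    (sin(phi) - sin(theta) / 16) * (cos(theta) - cos(phi))
  den <- 3 * (1 + 0.5 * (sqrt(5) - 1) * cos(theta) + 0.5 * (3 - sqrt(5)) * cos(phi))
  num / den
}

#' Build the standardized 60 x 60 x 60 4D LV mesh
#'
#' Interpolates anchor radii into two closed surfaces (endocardium and
#' epicardium) sampled at 60 angles around the z-axis, 60 apex-to-base
#' positions, and 60 uniform time points across the cardiac cycle.
#' Interpolation proceeds axis by axis: a closed periodic spline in angle
#' (6 to 60), then a natural cubic spline along z through the four slice
#' fractions extended by a zero-radius apex point at fraction 0, then a
#' periodic cubic spline in cycle phase resampled to 60 uniform phases.
#' All stages interpolate, so the mesh passes through every input anchor
#' radius.
#'
#' @param radii Anchor-radius tibble for one dataset: columns `frame`,
#'   `phase`, `theta_deg`, `boundary`, `z_frac`, `radius_mm` on the full
#'   48-anchor grid over at least 8 frames.
#' @param apex_z,base_z Apex/base axial positions per frame (mm).
#' @param cycle_duration_s Cycle length in seconds (carried into strain
#'   rates downstream).
#' @param n_out Samples per axis (default 60).
#' @param engine Curve engine for the angular stage (see
#'   [interpolate_closed_curve()]).
#' @return An object of class `lv_mesh`: `radii` array indexed
#'   `[boundary, angle, z, time]`, plus `angle_samples` (deg),
#'   `z_samples` (fractions), `time_samples` (phases), `apex_z`/`base_z`
#'   resampled to the 60 phases.
#' @export
build_lv_mesh <- function(radii, apex_z, base_z, cycle_duration_s = NA_real_,
                          n_out = 60, engine = "spline") {
  frames <- sort(unique(radii$frame))
  nf <- length(frames)
  if (nf < 8) abort("at least 8 frames are required to build a mesh")
  phases <- radii$phase[match(frames, radii$frame)]
  if (any(radii$radius_mm <= 0)) abort("all anchor radii must be strictly positive")
  apex_z <- rep_len(apex_z, nf); base_z <- rep_len(base_z, nf)

  angle_out <- seq(0, 360, length.out = n_out + 1)[-(n_out + 1)]
  z_out <- seq_len(n_out) / n_out
  t_out <- seq(0, 1, length.out = n_out + 1)[-(n_out + 1)]

  # dense lookup array of input radii [boundary, theta6, z4, frame]
  grid <- anchor_grid()
  R_in <- array(NA_real_, c(2, 6, 4, nf))
  bi <- match(radii$boundary, ANCHOR_BOUNDARIES)
  ti <- match(radii$theta_deg, ANCHOR_THETAS)
  zi <- match(radii$z_frac, ANCHOR_ZFRACS)
  fi <- match(radii$frame, frames)
  R_in[cbind(bi, ti, zi, fi)] <- radii$radius_mm
  if (anyNA(R_in)) abort("radii must cover the full 48-anchor grid at every frame")

  # stage 1: angle 6 -> n_out, per (boundary, z level, frame)
  A1 <- array(NA_real_, c(2, n_out, 4, nf))
  for (b in 1:2) for (zl in 1:4) for (f in seq_len(nf)) {
    A1[b, , zl, f] <- interpolate_closed_curve(R_in[b, , zl, f], angle_out,
                                               engine = engine)
  }
  # stage 2: z .25/.5/.75/1 -> n_out, per (boundary, angle, frame); a natural
  # spline through the four slice fractions, extrapolated linearly toward the
  # apex and floored positive. The apical closure itself (radius -> 0 exactly
  # at the apex) enters the volume integral as a zero-area terminal point, not
  # the surface interpolant, so an untapered wall keeps its radius down the
  # length of the ventricle.
  A2 <- array(NA_real_, c(2, n_out, n_out, nf))
  for (b in 1:2) for (f in seq_len(nf)) {
    vals <- t(A1[b, , , f]) # 4 x n_out angles
    for (a in seq_len(n_out)) {
      A2[b, a, , f] <- pmax(
        spline(ANCHOR_ZFRACS, vals[, a], method = "natural", xout = z_out)$y,
        1e-6)
    }
  }
  # stage 3: phase nf -> n_out uniform, per (boundary, angle, z)
  M <- array(NA_real_, c(2, n_out, n_out, n_out))
  for (b in 1:2) for (a in seq_len(n_out)) for (zz in seq_len(n_out)) {
    M[b, a, zz, ] <- .periodic_phase_spline(phases, A2[b, a, zz, ], t_out)
  }
  structure(list(
    radii = M, angle_samples = angle_out, z_samples = z_out,
    time_samples = t_out,
    apex_z = .periodic_phase_spline(phases, apex_z, t_out),
    base_z = .periodic_phase_spline(phases, base_z, t_out),
    cycle_duration_s = cycle_duration_s, engine = engine
  ), class = "lv_mesh")
}

#' @export
print.lv_mesh <- function(x, ...) {
  d <- dim(x$radii)
  cat(sprintf("<lv_mesh> 2 boundaries x %d angles x %d z x %d time samples (%s engine)\n",
              d[2], d[3], d[4], x$engine))
  invisible(x)
}

#' Evaluate the mesh interpolant at arbitrary coordinates
#'
#' Applies the same angle-then-z-then-time interpolation chain as
#' [build_lv_mesh()] but at a single (theta, z fraction, phase) query, so
#' anchor exactness and off-anchor behavior can be checked against the
#' analytic input without committing to the 60-sample grid.
#'
#' @inheritParams build_lv_mesh
#' @param theta_deg,z_frac,phase Query coordinates (scalars).
#' @param boundary `"endo"` or `"epi"`.
#' @return Radius in mm.
#' @export
mesh_radius_at <- function(radii, theta_deg, z_frac, phase,
                           boundary = "endo", engine = "spline") {
  frames <- sort(unique(radii$frame))
  phases <- radii$phase[match(frames, radii$frame)]
  sub <- radii[radii$boundary == boundary, ]
  # angle stage at each (z level, frame)
  at_z <- vapply(frames, function(f) {
    vapply(ANCHOR_ZFRACS, function(zf) {
      s <- sub[sub$frame == f & sub$z_frac == zf, ]
      s <- s[order(s$theta_deg), ]
      interpolate_closed_curve(s$radius_mm, theta_deg, engine = engine)
    }, numeric(1))
  }, numeric(4)) # 4 x nf
  # z stage per frame
  at_zf <- vapply(seq_along(frames), function(i) {
    pmax(spline(ANCHOR_ZFRACS, at_z[, i], method = "natural", xout = z_frac)$y,
         1e-6)
  }, numeric(1))
  # time stage
  .periodic_phase_spline(phases, at_zf, phase)
}

#' Export an LV mesh as a tidy point table
#'
#' @param mesh An [build_lv_mesh()] result.
#' @return Tibble with boundary, sample indices, radius and Cartesian
#'   coordinates (mm) for every mesh sample.
#' @export
mesh_points <- function(mesh) {
  d <- dim(mesh$radii)
  idx <- expand.grid(boundary = 1:2, angle_index = seq_len(d[2]),
                     z_index = seq_len(d[3]), t_index = seq_len(d[4]))
  th <- mesh$angle_samples[idx$angle_index] * pi / 180
  r <- mesh$radii[as.matrix(idx)]
  apex <- mesh$apex_z[idx$t_index]; base <- mesh$base_z[idx$t_index]
  tibble(
    boundary = ANCHOR_BOUNDARIES[idx$boundary],
    t_index = idx$t_index, z_index = idx$z_index, angle_index = idx$angle_index,
    radius_mm = r,
    x_mm = r * cos(th), y_mm = r * sin(th),
    z_mm = apex + mesh$z_samples[idx$z_index] * (base - apex)
  )
}
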