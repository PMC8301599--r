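# closed polyline length of a contour given by radii at angles (radians)
.closed_perimeter <- function(r, th) {
  x <- r * cos(th); y <- r * sin(th)
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Circumferential Lagrangian strain
#'
#' For each requested z sample and time point, the endo- or epi-cardial
#' contour's closed polyline perimeter is compared to its end-diastolic
#' (t = 0) value: `strain = (perimeter_t - perimeter_0) / perimeter_0`.
#'
#' @param mesh An [build_lv_mesh()] result.
#' @param boundary `"endo"` (default) or `"epi"`.
#' @param z_index Which z samples to report (default all 60).
#' @return Tibble with `z_index`, `z_frac`, `phase`, `time_s`, `strain`.
#' @export
circumferential_strain <- function(mesh, boundary = "endo",
                                   z_index = seq_along(mesh$z_samples)) {
  b <- match(boundary, ANCHOR_BOUNDARIES)
  th <- mesh$angle_samples * pi / 180
  purrr::map_dfr(z_index, function(zz) {
    per <- vapply(seq_along(mesh$time_samples), function(tt) {
      r <- mesh$radii[b, , zz, tt]
      if (sum(abs(diff(r)) > 0) == 0 && r[1] <= 0) abort("degenerate contour")
      .closed_perimeter(r, th)
    }, numeric(1))
    tibble(
      z_index = zz, z_frac = mesh$z_samples[zz],
      phase = mesh$time_samples,
      time_s = mesh$time_samples * mesh$cycle_duration_s,
      strain = (per - per[1]) / per[1]
    )
  })
}

#' Longitudinal Lagrangian strain
#'
#' For each requested rotation, the apex-to-base surface polyline at that
#' fixed angle (through the 60 z samples, using full 3D coordinates with
#' the per-frame apex/base axial positions) is measured at every time
#' point and compared to end-diastole:
#' `strain = (length_t - length_0) / length_0`.
#'
#' @param mesh An [build_lv_mesh()] result.
#' @param boundary `"endo"` or `"epi"`.
#' @param angle_index Which angle samples to report (default: the six
#'   standard rotations).
#' @return Tibble with `angle_index`, `theta_deg`, `phase`, `time_s`,
#'   `strain`.
#' @export
longitudinal_strain <- function(mesh, boundary = "endo",
                                angle_index = NULL) {
  b <- match(boundary, ANCHOR_BOUNDARIES)
  if (is.null(angle_index)) {
    angle_index <- match(ANCHOR_THETAS, round(mesh$angle_samples, 6))
    if (anyNA(angle_index)) angle_index <- seq_along(mesh$angle_samples)
  }
  purrr::map_dfr(angle_index, function(a) {
    th <- mesh$angle_samples[a] * pi / 180
    len <- vapply(seq_along(mesh$time_samples), function(tt) {
      r <- mesh$radii[b, a, , tt]
      z <- mesh$apex_z[tt] + mesh$z_samples * (mesh$base_z[tt] - mesh$apex_z[tt])
      x <- r * cos(th); y <- r * sin(th)
      sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
    }, numeric(1))
    tibble(
      angle_index = a, theta_deg = mesh$angle_samples[a],
      phase = mesh$time_samples,
      time_s = mesh$time_samples * mesh$cycle_duration_s,
      strain = (len - len[1]) / len[1]
    )
  })
}

#' Early/late systolic and diastolic strain rates
#'
#' The cycle is split at peak systole into a systolic window
#' `[0, ps_phase]` and a diastolic window `[ps_phase, 1]`; each window is
#' halved at its midpoint into early and late parts, and the rate is the
#' slope (1/s) of an ordinary least-squares line fit to strain versus
#' time within each half-window.
#'
#' @param strain Strain values sampled at `phases`.
#' @param phases Cycle fractions of the samples (uniform mesh sampling).
#' @param ps_phase Peak-systole phase, strictly inside (0, 1).
#' @param cycle_duration_s Cycle length in seconds.
#' @return A tibble with one row per window: `window` in
#'   `early_systolic`, `late_systolic`, `early_diastolic`,
#'   `late_diastolic`, and `rate_per_s`.
#' @export
strain_rates <- function(strain, phases, ps_phase, cycle_duration_s) {
  if (ps_phase <= 0 || ps_phase >= 1) abort("ps_phase must lie strictly in (0, 1)")
  windows <- list(
    early_systolic = c(0, ps_phase / 2),
    late_systolic = c(ps_phase / 2, ps_phase),
    early_diastolic = c(ps_phase, ps_phase + (1 - ps_phase) / 2),
    late_diastolic = c(ps_phase + (1 - ps_phase) / 2, 1)
  )
  t_s <- phases * cycle_duration_s
  purrr::imap_dfr(windows, function(w, nm) {
    sel <- phases >= w[1] - 1e-12 & phases <= w[2] + 1e-12
    if (sum(sel) < 3) {
      abort(sprintf("window %s has %d samples; need at least 3", nm, sum(sel)))
    }
    tibble(window = nm,
           rate_per_s = unname(coef(lm(strain[sel] ~ t_s[sel]))[2]))
  })
}

# cavity cross-sectional area by the shoelace formula
.shoelace <- function(x, y) {
  xs <- c(x, x[1]); ys <- c(y, y[1])
  0.5 * abs(sum(xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)]))
}

#' Cavity volume over the cycle and global function metrics
#'
#' The endocardial cavity volume at each time point is a trapezoidal sum
#' over z of the shoelace polygon area of the 60-point contour, including
#' the apex closure (area tapering to zero at the apex). End-diastolic
#' volume (EDV) is the volume at phase 0; peak-systolic volume (PSV) is
#' the minimum over phases (earliest on ties); stroke volume
#' SV = EDV - PSV and ejection fraction EF = 100 * SV / EDV. Volumes are
#' in microliters (1 mm^3 = 1 uL).
#'
#' @param mesh An [build_lv_mesh()] result.
#' @return A list with `volumes` (tibble of phase, volume_ul), `edv_ul`,
#'   `psv_ul`, `sv_ul`, `ef_pct`, and `ps_phase` (phase of the volume
#'   minimum).
#' @export
global_function <- function(mesh) {
  b <- match("endo", ANCHOR_BOUNDARIES)
  th <- mesh$angle_samples * pi / 180
  vols <- vapply(seq_along(mesh$time_samples), function(tt) {
    areas <- vapply(seq_along(mesh$z_samples), function(zz) {
      r <- mesh$radii[b, , zz, tt]
      .shoelace(r * cos(th), r * sin(th))
    }, numeric(1))
    z_mm <- mesh$apex_z[tt] + mesh$z_samples * (mesh$base_z[tt] - mesh$apex_z[tt])
    # apex closure: area 0 at the apex itself
    z_all <- c(mesh$apex_z[tt], z_mm)
    a_all <- c(0, areas)
    sum(diff(z_all) * (head(a_all, -1) + tail(a_all, -1)) / 2)
  }, numeric(1))
  edv <- vols[1]
  if (edv <= 0) abort("end-diastolic volume is zero; invalid mesh")
  imin <- which.min(vols) # which.min returns the earliest minimum on ties
  psv <- vols[imin]
  list(
    volumes = tibble(phase = mesh$time_samples, volume_ul = vols),
    edv_ul = edv, psv_ul = psv, sv_ul = edv - psv,
    ef_pct = 100 * (edv - psv) / edv,
    ps_phase = mesh$time_samples[imin]
  )
}

#' Kinematic metric table for one mesh
#'
#' Computes the standard per-location curve metrics and global function
#' block: peak strain (signed extremum) plus the four early/late
#' systolic/diastolic strain rates for circumferential strain at the
#' basal (z = 1.00), mid-LV (0.50) and apical (0.25) levels and for
#' longitudinal strain at the six standard rotations, and EDV, PSV, SV,
#' EF from the cavity volume. Peak systole is located once, globally,
#' from the endocardial cavity-volume minimum so all curves share one
#' phase landmark.
#'
#' @param mesh An [build_lv_mesh()] result (with `cycle_duration_s` set).
#' @param boundary Boundary for the strain metrics (default `"endo"`).
#' @param ps_phase Peak-systole phase; derived from the cavity volume
#'   minimum when `NULL`.
#' @return Tidy tibble with columns `metric`, `frame_type` (`circ`,
#'   `long`, `global`), `location`, `boundary`, `value`, `units`.
#' @export
metric_table <- function(mesh, boundary = "endo", ps_phase = NULL) {
  gf <- global_function(mesh)
  if (is.null(ps_phase)) ps_phase <- gf$ps_phase
  if (ps_phase <= 0) ps_phase <- 0.35 # time-constant mesh: fall back
  circ_locs <- c(basal = 1.00, `mid-LV` = 0.50, apical = 0.25)
  rows <- list()
  for (i in seq_along(circ_locs)) {
    zz <- which.min(abs(mesh$z_samples - circ_locs[i]))
    cs <- circumferential_strain(mesh, boundary, zz)
    rows[[length(rows) + 1]] <- .curve_metrics(cs$strain, cs$phase, ps_phase,
                                               mesh$cycle_duration_s,
                                               "circ", names(circ_locs)[i], boundary)
  }
  aidx <- vapply(ANCHOR_THETAS, function(a) which.min(abs(mesh$angle_samples - a)),
                 integer(1))
  for (i in seq_along(aidx)) {
    ls <- longitudinal_strain(mesh, boundary, aidx[i])
    rows[[length(rows) + 1]] <- .curve_metrics(ls$strain, ls$phase, ps_phase,
                                               mesh$cycle_duration_s,
                                               "long", ROTATION_LABELS[[i]], boundary)
  }
  glob <- tibble(
    metric = c("edv", "psv", "sv", "ef"),
    frame_type = "global", location = "global", boundary = "endo",
    value = c(gf$edv_ul, gf$psv_ul, gf$sv_ul, gf$ef_pct),
    units = c("uL", "uL", "uL", "%")
  )
  dplyr::bind_rows(dplyr::bind_rows(rows), glob)
}

.curve_metrics <- function(strain, phases, ps_phase, cycle_s, frame_type,
                           location, boundary) {
  peak <- strain[which.max(abs(strain))]
  sr <- strain_rates(strain, phases, ps_phase, cycle_s)
  tibble(
    metric = c("peak_strain", paste0(sr$window, "_strain_rate")),
    frame_type = frame_type, location = location, boundary = boundary,
    value = c(peak, sr$rate_per_s),
    units = c("dimensionless", rep("1/s", 4))
  )
}
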