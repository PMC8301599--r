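#' Cine dataset container
#'
#' One animal's 4D grayscale ultrasound-like recording: an intensity stack
#' indexed (frame, stored slice, row, column) plus the metadata needed to
#' place it in the standard frame — pixel spacing, the axial positions of
#' the stored slices, the cardiac cycle phase of each frame, and per-frame
#' apex/base axial tracks.
#'
#' @param intensities 4D numeric array `(t, z, y, x)`.
#' @param pixel_spacing In-plane spacing, mm/pixel.
#' @param slice_z Axial positions (mm) of the stored slices, strictly
#'   increasing; its spacing defines the slice spacing.
#' @param cycle_phase Per-frame cycle fraction in `[0, 1)`, first frame at
#'   phase 0 (end-diastole), strictly increasing.
#' @param apex_z,base_z Per-frame axial apex and base positions (mm);
#'   `apex_z < base_z` at every frame.
#' @param animal_id Identifier string.
#' @param cycle_duration_s Duration of one cardiac cycle in seconds.
#' @return An object of class `cine_dataset`.
#' @export
cine_dataset <- function(intensities, pixel_spacing, slice_z, cycle_phase,
                         apex_z, base_z, animal_id, cycle_duration_s) {
  stopifnot(length(dim(intensities)) == 4)
  nt <- dim(intensities)[1]
  apex_z <- rep_len(apex_z, nt)
  base_z <- rep_len(base_z, nt)
  if (any(apex_z >= base_z)) abort("apex_z must be below base_z at every frame")
  if (cycle_phase[1] != 0 || any(diff(cycle_phase) <= 0)) {
    abort("cycle_phase must start at 0 and increase strictly")
  }
  if (any(diff(slice_z) <= 0)) abort("slice_z must be strictly increasing")
  structure(
    list(intensities = intensities, pixel_spacing = pixel_spacing,
         slice_z = slice_z, slice_spacing = mean(diff(slice_z)),
         cycle_phase = cycle_phase, apex_z = apex_z, base_z = base_z,
         animal_id = as.character(animal_id),
         cycle_duration_s = cycle_duration_s),
    class = "cine_dataset"
  )
}

#' @export
print.cine_dataset <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<cine_dataset %s> %d frames x %d slices x %dx%d px (%.3f mm/px), cycle %.3f s\n",
    x$animal_id, d[1], d[2], d[3], d[4], x$pixel_spacing, x$cycle_duration_s
  ))
  invisible(x)
}

#' Phantom configuration
#'
#' Parameters of the synthetic beating-LV cine phantom. Defaults describe
#' a healthy adult mouse: endocardial end-diastolic radius ~1.5 mm, wall
#' ~0.8 mm, heart rate 500 bpm, ~25% peak radial contraction at phase
#' 0.35, with per-animal heart-size offsets and smooth regional variation
#' in contraction amplitude. Speckle is multiplicative Rayleigh-like
#' noise; an optional angular shadow sector emulates the sternum shadow
#' over the basal posterior septum.
#'
#' @param n_animals Number of animals in the cohort.
#' @param frames_per_cycle Temporal samples per cardiac cycle (>= 8).
#' @param image_size Pixels per image side.
#' @param pixel_spacing mm per pixel.
#' @param n_slices_stored Stored z samples spanning apex to base.
#' @param endo_radius_ed Per-animal mean basal endocardial radius at
#'   end-diastole, mm.
#' @param endo_radius_sd Between-animal SD of that radius, mm (the
#'   "heart-size offset").
#' @param wall_thickness_ed End-diastolic wall thickness, mm.
#' @param contraction_fraction Peak radial contraction of the endocardium,
#'   dimensionless in `[0, 1)`.
#' @param regional_amplitude_sd SD of the smooth per-animal regional
#'   perturbation of contraction amplitude (relative).
#' @param longitudinal_shortening Peak fractional apex-to-base shortening.
#' @param ps_phase Cycle phase of peak systole.
#' @param speckle_scale Speckle strength in `[0, 1]`; 0 disables noise.
#' @param shadow List: `enabled`, `center_deg`, `extent_deg`,
#'   `attenuation` (intensity multiplier), `z_frac_range` (affected
#'   apex-to-base range).
#' @param heart_rate_bpm Heart rate, beats per minute.
#' @param seed Integer seed making generation a pure function of config.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(n_animals,
                           frames_per_cycle = 32,
                           image_size = 128,
                           pixel_spacing = 0.05,
                           n_slices_stored = 16,
                           endo_radius_ed = 1.5,
                           endo_radius_sd = 0.2,
                           wall_thickness_ed = 0.8,
                           contraction_fraction = 0.25,
                           regional_amplitude_sd = 0.10,
                           longitudinal_shortening = 0.12,
                           ps_phase = 0.35,
                           speckle_scale = 0.3,
                           shadow = list(enabled = TRUE, center_deg = 225,
                                         extent_deg = 60, attenuation = 0.45,
                                         z_frac_range = c(0.75, 1.0)),
                           heart_rate_bpm = 500,
                           seed = 1L) {
  cfg <- list(
    n_animals = as.integer(n_animals), frames_per_cycle = as.integer(frames_per_cycle),
    image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
    n_slices_stored = as.integer(n_slices_stored),
    endo_radius_ed = endo_radius_ed, endo_radius_sd = endo_radius_sd,
    wall_thickness_ed = wall_thickness_ed,
    contraction_fraction = contraction_fraction,
    regional_amplitude_sd = regional_amplitude_sd,
    longitudinal_shortening = longitudinal_shortening,
    ps_phase = ps_phase, speckle_scale = speckle_scale, shadow = shadow,
    heart_rate_bpm = heart_rate_bpm, seed = as.integer(seed)
  )
  if (cfg$n_animals < 1) abort("n_animals must be >= 1")
  if (cfg$frames_per_cycle < 8) abort("frames_per_cycle must be >= 8")
  if (cfg$contraction_fraction < 0 || cfg$contraction_fraction >= 1) {
    abort("contraction_fraction must lie in [0, 1)")
  }
  if (cfg$ps_phase <= 0 || cfg$ps_phase >= 1) abort("ps_phase must lie in (0, 1)")
  fov <- cfg$image_size * cfg$pixel_spacing / 2
  reach <- cfg$endo_radius_ed + 3 * cfg$endo_radius_sd + cfg$wall_thickness_ed
  if (reach >= fov) {
    abort(sprintf("heart (up to %.2f mm) does not fit in the %.2f mm half field of view",
                  reach, fov))
  }
  structure(cfg, class = "phantom_config")
}

#' Periodic radial contraction waveform
#'
#' Radius of a contracting wall point as a smooth periodic function of
#' cycle phase: `r(phase) = r_ed * (1 - contraction * g(phase))`, where
#' `g` is a raised-cosine bump with `g(0) = 0` at end-diastole,
#' `g(ps_phase) = 1` at peak systole, and a continuous first derivative
#' everywhere including the cycle wrap.
#'
#' @param phase Cycle fraction(s); values outside `[0, 1)` are wrapped.
#' @param r_ed End-diastolic radius, mm.
#' @param contraction Peak fractional contraction in `[0, 1)`.
#' @param ps_phase Phase of peak systole, strictly inside `(0, 1)`.
#' @return Radius in mm, vectorized over `phase`.
#' @examples
#' radius_waveform(0, 2, 0.25)        # end-diastole: 2
#' radius_waveform(0.35, 2, 0.25)     # peak systole: 1.5
#' @export
radius_waveform <- function(phase, r_ed, contraction, ps_phase = 0.35) {
  if (any(contraction < 0) || any(contraction >= 1)) {
    abort("contraction must lie in [0, 1)")
  }
  if (ps_phase <= 0 || ps_phase >= 1) abort("ps_phase must lie strictly in (0, 1)")
  r_ed * (1 - contraction * .contraction_bump(phase, ps_phase))
}

# Raised-cosine bump g: g(0)=0, g(ps)=1, C1 across both ps and the wrap
# (derivative 0 at phase 0, ps, and 1).
.contraction_bump <- function(phase, ps_phase) {
  p <- phase %% 1
  ifelse(p <= ps_phase,
         0.5 * (1 - cos(pi * p / ps_phase)),
         0.5 * (1 - cos(pi * (1 - p) / (1 - ps_phase))))
}

#' Render one synthetic short-axis image
#'
#' Draws a bright myocardial annulus between endo- and epi-cardial
#' contours given as radii per angle (interpolated periodically between
#' the supplied angles), over a darker cavity and background; then applies
#' multiplicative Rayleigh-like speckle and, optionally, an attenuated
#' angular shadow sector. Rendering is deterministic given `seed`.
#'
#' @param endo_radii,epi_radii Radii in mm at `angles_deg`;
#'   `epi_radii > endo_radii` must hold at every angle.
#' @param angles_deg Angles (degrees) at which the radii are given.
#' @param image_size Pixels per side.
#' @param pixel_spacing mm per pixel; the image center is the z-axis.
#' @param speckle_scale Speckle strength in `[0, 1]` (0 = noiseless).
#' @param shadow `NULL` or a list as in [phantom_config()].
#' @param seed Integer seed for the speckle draw.
#' @return `image_size` x `image_size` numeric matrix in `[0, ~1.5]`.
#' @export
render_short_axis <- function(endo_radii, epi_radii, angles_deg = NULL,
                              image_size = 128, pixel_spacing = 0.05,
                              speckle_scale = 0, shadow = NULL, seed = NULL) {
  n_ang <- length(endo_radii)
  if (is.null(angles_deg)) angles_deg <- seq(0, 360, length.out = n_ang + 1)[-(n_ang + 1)]
  stopifnot(length(epi_radii) == n_ang, length(angles_deg) == n_ang)
  if (any(epi_radii <= endo_radii)) {
    abort("epicardial radius must exceed endocardial radius at every angle")
  }
  geo <- .pixel_polar(image_size, pixel_spacing)
  r_endo <- .interp_periodic(angles_deg, endo_radii, geo$theta)
  r_epi <- .interp_periodic(angles_deg, epi_radii, geo$theta)
  img <- matrix(0.30, image_size, image_size) # background
  img[geo$r <= r_epi] <- 0.90                 # myocardial wall
  img[geo$r < r_endo] <- 0.10                 # blood pool
  if (!is.null(shadow) && isTRUE(shadow$enabled)) {
    half <- shadow$extent_deg / 2
    dth <- abs(((geo$theta - shadow$center_deg + 180) %% 360) - 180)
    img[dth <= half] <- img[dth <= half] * shadow$attenuation
  }
  if (speckle_scale > 0) {
    draw <- function() {
      ray <- sqrt(-2 * log(runif(image_size^2)))  # Rayleigh(1), mean sqrt(pi/2)
      mult <- (1 - speckle_scale) + speckle_scale * ray / sqrt(pi / 2)
      img * matrix(mult, image_size, image_size)
    }
    img <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  img
}

# polar coordinates of pixel centers; image center is the origin, +y up.
.pixel_polar <- function(n, spacing) {
  x <- matrix((seq_len(n) - (n + 1) / 2) * spacing, n, n, byrow = TRUE)
  y <- matrix(((n + 1) / 2 - seq_len(n)) * spacing, n, n)
  list(r = sqrt(x^2 + y^2), theta = (atan2(y, x) * 180 / pi) %% 360)
}

# periodic linear interpolation of radii given at angles (degrees)
.interp_periodic <- function(angles, values, at) {
  o <- order(angles)
  a <- angles[o]; v <- values[o]
  a_ext <- c(a[length(a)] - 360, a, a[1] + 360)
  v_ext <- c(v[length(v)], v, v[1])
  res <- approx(a_ext, v_ext, xout = ((at - a[1]) %% 360) + a[1], rule = 2)$y
  res
}

# ---- analytic per-animal boundary model -----------------------------------

# Ellipsoid-like apex-to-base taper for the endocardium; the epicardium
# keeps a finite apical cap (wall thickness persists at the apex).
.endo_shape <- function(z_frac) sqrt(pmax(z_frac, 0) * (2 - pmax(z_frac, 0)))

# animal: list(r_ed, wall, amp_coef = c(a1, b1, c1), contraction).
# Fully vectorized over theta/z/phase/boundary (recycled to equal length).
.animal_radius <- function(animal, theta_deg, z_frac, phase, boundary, ps_phase) {
  n <- max(length(theta_deg), length(z_frac), length(phase), length(boundary))
  theta_deg <- rep_len(theta_deg, n); z_frac <- rep_len(z_frac, n)
  phase <- rep_len(phase, n); boundary <- rep_len(boundary, n)
  th <- theta_deg * pi / 180
  endo_ed <- animal$r_ed * .endo_shape(z_frac)
  epi_ed <- endo_ed + animal$wall * (0.6 + 0.4 * z_frac)
  amp <- animal$contraction *
    (1 + animal$amp_coef[1] * cos(th) + animal$amp_coef[2] * sin(th) +
       animal$amp_coef[3] * (z_frac - 0.625))
  amp <- pmin(pmax(amp, 0), 0.9)
  g <- .contraction_bump(phase, ps_phase)
  # epicardial amplitude scaled down so the wall thickens through systole
  amp_epi <- 0.6 * amp * endo_ed / epi_ed
  ifelse(boundary == "endo", endo_ed * (1 - amp * g), epi_ed * (1 - amp_epi * g))
}

#' Generate a synthetic 4DUS cohort with known ground truth
#'
#' Draws per-animal heart geometry (end-diastolic radius from the
#' configured mean/SD — the heart-size offset an assisted model can
#' exploit — plus a smooth regional perturbation of contraction
#' amplitude), renders every stored short-axis slice of every frame with
#' speckle and shadow, and returns both the cine stacks and the exact
#' anchor-radius ground truth used to render them. Generation is a pure
#' function of `(config, seed)`.
#'
#' @param config A [phantom_config()].
#' @param render_images If `FALSE`, skip image rendering and return only
#'   ground truth (useful for distributional checks on large cohorts).
#' @return A tibble with one row per animal and columns `animal_id`,
#'   `dataset` (list of [cine_dataset()] or `NULL`), `truth` (list of
#'   anchor-radius tibbles with columns `frame`, `phase`, `theta_deg`,
#'   `boundary`, `z_frac`, `radius_mm`). The config is attached as the
#'   `"config"` attribute.
#' @export
generate_cohort <- function(config, render_images = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, .generate_cohort_impl(config, render_images))
}

.generate_cohort_impl <- function(cfg, render_images) {
  grid <- anchor_grid()
  phases <- seq(0, 1 - 1 / cfg$frames_per_cycle, length.out = cfg$frames_per_cycle)
  apex0 <- 0
  L0 <- 6.5 # apex-to-base length at end-diastole, mm
  slice_z <- seq(apex0, apex0 + L0, length.out = cfg$n_slices_stored)
  cycle_s <- 60 / cfg$heart_rate_bpm
  dense_angles <- seq(0, 359, by = 3)

  # all stochastic per-animal parameters are drawn up front, so the ground
  # truth is identical whether or not images are rendered
  animals <- purrr::map(seq_len(cfg$n_animals), function(i) {
    a <- list(
      r_ed = rnorm(1, cfg$endo_radius_ed, cfg$endo_radius_sd),
      wall = cfg$wall_thickness_ed,
      amp_coef = rnorm(3, 0, cfg$regional_amplitude_sd),
      contraction = cfg$contraction_fraction
    )
    a$r_ed <- max(a$r_ed, 0.5) # keep geometry sane in extreme draws
    a
  })

  rows <- purrr::map(seq_len(cfg$n_animals), function(i) {
    animal <- animals[[i]]
    base_z <- apex0 + L0 * (1 - cfg$longitudinal_shortening *
                              .contraction_bump(phases, cfg$ps_phase))
    truth <- tidyr::expand_grid(frame = seq_along(phases), grid) |>
      dplyr::mutate(
        phase = phases[.data$frame],
        radius_mm = .animal_radius(animal, .data$theta_deg, .data$z_frac,
                                   .data$phase, .data$boundary, cfg$ps_phase)
      ) |>
      dplyr::select("frame", "phase", "theta_deg", "boundary", "z_frac",
                    "radius_mm", "anchor_id")

    ds <- NULL
    if (render_images) {
      stack <- array(0, dim = c(cfg$frames_per_cycle, cfg$n_slices_stored,
                                cfg$image_size, cfg$image_size))
      seeds <- sample.int(.Machine$integer.max %/% 2,
                          cfg$frames_per_cycle * cfg$n_slices_stored)
      k <- 0
      for (ti in seq_along(phases)) {
        for (zi in seq_len(cfg$n_slices_stored)) {
          k <- k + 1
          zf <- (slice_z[zi] - apex0) / (base_z[ti] - apex0)
          if (zf <= 0.02 || zf > 1) {
            img <- matrix(0.30, cfg$image_size, cfg$image_size)
            if (cfg$speckle_scale > 0) {
              img <- withr::with_seed(seeds[k], {
                ray <- sqrt(-2 * log(runif(cfg$image_size^2)))
                img * matrix((1 - cfg$speckle_scale) +
                               cfg$speckle_scale * ray / sqrt(pi / 2),
                             cfg$image_size, cfg$image_size)
              })
            }
          } else {
            endo <- .animal_radius(animal, dense_angles, zf, phases[ti], "endo", cfg$ps_phase)
            epi <- .animal_radius(animal, dense_angles, zf, phases[ti], "epi", cfg$ps_phase)
            sh <- cfg$shadow
            in_range <- isTRUE(sh$enabled) &&
              zf >= sh$z_frac_range[1] && zf <= sh$z_frac_range[2]
            img <- render_short_axis(
              endo, epi, dense_angles, cfg$image_size, cfg$pixel_spacing,
              speckle_scale = cfg$speckle_scale,
              shadow = if (in_range) sh else NULL, seed = seeds[k]
            )
          }
          stack[ti, zi, , ] <- img
        }
      }
      ds <- cine_dataset(stack, cfg$pixel_spacing, slice_z, phases,
                         apex_z = rep(apex0, length(phases)), base_z = base_z,
                         animal_id = sprintf("animal%03d", i),
                         cycle_duration_s = cycle_s)
    }
    list(animal_id = sprintf("animal%03d", i), dataset = ds, truth = truth)
  })

  out <- tibble(
    animal_id = purrr::map_chr(rows, "animal_id"),
    dataset = purrr::map(rows, "dataset"),
    truth = purrr::map(rows, "truth")
  )
  attr(out, "config") <- cfg
  out
}

#' Bind a cohort's ground-truth anchor radii into one tibble
#'
#' @param cohort A cohort tibble from [generate_cohort()] or
#'   [generate_linear_cohort()].
#' @return A tibble of anchor radii with an `animal_id` column.
#' @export
cohort_truth <- function(cohort) {
  cohort |>
    dplyr::select("animal_id", "truth") |>
    tidyr::unnest("truth")
}

#' Generate a cohort drawn exactly from the regression model family
#'
#' Builds cine-like datasets whose slice images are low-rank: each frame's
#' four-slice pixel vector is a fixed mean pattern plus a linear
#' combination of `k_true` orthonormal pixel patterns, with latent scores
#' that are smooth functions of cycle phase plus a per-animal size offset.
#' Anchor radii are exact linear functions of those same latent scores, so
#' a principal-component regression with enough components can predict
#' them perfectly in the noiseless case. This is the reference cohort for
#' parameter-recovery and no-signal null checks.
#'
#' @param n_animals,frames_per_cycle,image_size Cohort dimensions; each
#'   frame stores exactly the four standard slices.
#' @param k_true Number of latent pixel patterns.
#' @param size_sd SD of the per-animal size offset (mm).
#' @param pixel_noise_sd Additive iid pixel noise (0 = noiseless).
#' @param radius_noise_sd Additive iid noise on the anchor radii, mm.
#' @param image_signal If `"latent"`, images carry the latent scores; if
#'   `"noise"`, images are pure noise and carry no information about the
#'   radii (for assisted-model and no-signal checks).
#' @param radius_signal If `"latent"`, radii are exact linear functions of
#'   the latent scores; if `"none"`, radii are a constant per anchor plus
#'   `radius_noise_sd` noise (the no-signal null, where no model should
#'   beat the test-mean baseline).
#' @param seed Integer seed.
#' @return A cohort tibble as in [generate_cohort()].
#' @export
generate_linear_cohort <- function(n_animals, frames_per_cycle = 20,
                                   image_size = 24, k_true = 3,
                                   size_sd = 0.2, pixel_noise_sd = 0,
                                   radius_noise_sd = 0,
                                   image_signal = c("latent", "noise"),
                                   radius_signal = c("latent", "none"),
                                   seed = 1L) {
  image_signal <- match.arg(image_signal)
  radius_signal <- match.arg(radius_signal)
  withr::with_seed(as.integer(seed), {
    grid <- anchor_grid()
    phases <- seq(0, 1 - 1 / frames_per_cycle, length.out = frames_per_cycle)
    p_slice <- image_size^2
    p_all <- 4 * p_slice
    Q <- qr.Q(qr(matrix(rnorm(p_all * k_true), p_all, k_true)))
    mean_pat <- runif(p_all, 0.2, 0.6)
    # per-anchor linear map from latent scores to radius
    base_r <- 1.2 + 0.6 * grid$z_frac + ifelse(grid$boundary == "epi", 0.8, 0)
    B <- matrix(rnorm(48 * k_true, 0, 0.08), k_true, 48)
    apex0 <- 0; L0 <- 6.5
    slice_z <- apex0 + ANCHOR_ZFRACS * L0

    rows <- purrr::map(seq_len(n_animals), function(i) {
      size <- rnorm(1, 0, size_sd)
      ph_feats <- cbind(cos(2 * pi * phases), sin(2 * pi * phases),
                        cos(4 * pi * phases))[, seq_len(min(3, k_true)), drop = FALSE]
      S <- matrix(0, frames_per_cycle, k_true)
      S[, seq_len(ncol(ph_feats))] <- ph_feats
      S <- S + size # per-animal offset enters every latent coordinate
      radii <- matrix(base_r, frames_per_cycle, 48, byrow = TRUE)
      if (radius_signal == "latent") radii <- radii + S %*% B
      if (radius_noise_sd > 0) {
        radii <- radii + matrix(rnorm(length(radii), 0, radius_noise_sd),
                                nrow(radii))
      }
      radii <- pmax(radii, 0.05)
      truth <- tidyr::expand_grid(frame = seq_along(phases), grid) |>
        dplyr::mutate(
          phase = phases[.data$frame],
          radius_mm = radii[cbind(.data$frame,
                                  rep(seq_len(48), frames_per_cycle))]
        ) |>
        dplyr::select("frame", "phase", "theta_deg", "boundary", "z_frac",
                      "radius_mm", "anchor_id")
      X <- if (image_signal == "latent") {
        matrix(mean_pat, frames_per_cycle, p_all, byrow = TRUE) + S %*% t(Q)
      } else {
        matrix(mean_pat, frames_per_cycle, p_all, byrow = TRUE)
      }
      if (pixel_noise_sd > 0 || image_signal == "noise") {
        sdn <- if (image_signal == "noise") max(pixel_noise_sd, 0.05) else pixel_noise_sd
        X <- X + matrix(rnorm(length(X), 0, sdn), nrow(X))
      }
      stack <- array(0, dim = c(frames_per_cycle, 4, image_size, image_size))
      for (ti in seq_len(frames_per_cycle)) {
        for (si in 1:4) {
          v <- X[ti, ((si - 1) * p_slice + 1):(si * p_slice)]
          stack[ti, si, , ] <- matrix(v, image_size, image_size, byrow = TRUE)
        }
      }
      ds <- cine_dataset(stack, pixel_spacing = 0.05, slice_z = slice_z,
                         cycle_phase = phases, apex_z = rep(apex0, frames_per_cycle),
                         base_z = rep(apex0 + L0, frames_per_cycle),
                         animal_id = sprintf("animal%03d", i),
                         cycle_duration_s = 0.12)
      list(animal_id = ds$animal_id, dataset = ds, truth = truth)
    })
    out <- tibble(
      animal_id = purrr::map_chr(rows, "animal_id"),
      dataset = purrr::map(rows, "dataset"),
      truth = purrr::map(rows, "truth")
    )
    attr(out, "linear_family") <- TRUE
    out
  })
}
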