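# Shared fixtures, built in code at test time.

# A desk-scale phantom configuration: 48 px frames at the full 6.4 mm field
# of view, 12 frames, 8 stored slices.
tiny_phantom_config <- function(n_animals = 2, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_animals = n_animals, frames_per_cycle = 12, image_size = 48,
         pixel_spacing = 6.4 / 48, n_slices_stored = 8, seed = seed),
    list(...)
  )
  do.call(phantom_config, args)
}

# Anchor-radius table for a constant-in-time tube (endo r_endo, epi r_epi)
# over `nf` frames.
tube_radii <- function(r_endo = 2, r_epi = 2.5, nf = 10) {
  phases <- seq(0, 1 - 1 / nf, length.out = nf)
  tidyr::expand_grid(frame = seq_len(nf), anchor_grid()) |>
    dplyr::mutate(phase = phases[frame],
                  radius_mm = ifelse(boundary == "endo", r_endo, r_epi))
}

# Independent Cox-de Boor recursion for B-spline evaluation (the oracle for
# evaluate_time_basis); returns the full basis row at x for given knots/order.
deboor_row <- function(x, knots, ord = 4) {
  nb <- length(knots) - ord
  B <- sapply(seq_len(length(knots) - 1), function(i) {
    as.numeric(knots[i] <= x & x < knots[i + 1])
  })
  for (k in 2:ord) {
    Bnew <- numeric(length(knots) - k)
    for (i in seq_len(length(knots) - k)) {
      a <- if (knots[i + k - 1] > knots[i]) {
        (x - knots[i]) / (knots[i + k - 1] - knots[i]) * B[i]
      } else 0
      b <- if (knots[i + k] > knots[i + 1]) {
        (knots[i + k] - x) / (knots[i + k] - knots[i + 1]) * B[i + 1]
      } else 0
      Bnew[i] <- a + b
    }
    B <- Bnew
  }
  B[seq_len(nb)]
}

# Periodic fold of the de Boor row matching the package's uniform-knot
# construction.
periodic_deboor_row <- function(x, nb) {
  knots <- seq(-3, nb + 3) / nb
  row <- deboor_row(x, knots, 4)
  out <- row[1:nb]
  out[1:3] <- out[1:3] + row[(nb + 1):(nb + 3)]
  out
}

# First cavity-to-wall edge along the +y ray of a rendered image, in mm from
# the center: the ray-casting oracle for comparing renders against
# ground-truth radii.
edge_along_ray_mm <- function(img, pixel_spacing, threshold = 0.5) {
  n <- nrow(img)
  cx <- (n + 1) / 2
  colx <- ceiling(cx)              # column with x nearest 0
  rows <- seq(floor(cx), 1)        # walk outward from the center along +y
  y <- (cx - rows) * pixel_spacing # y coordinate of each pixel center
  prof <- img[rows, colx]
  hit <- which(prof >= threshold)[1]
  if (is.na(hit) || hit == 1) return(NA_real_)
  (y[hit - 1] + y[hit]) / 2
}
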