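#' Write / read a cine dataset as multi-page TIFF plus JSON sidecar
#'
#' The intensity stack is stored as one 32-bit float TIFF page per
#' (frame, slice), frame-major, and all metadata (pixel spacing, slice
#' positions, cycle phases, apex/base tracks, cycle duration, animal id)
#' goes in a JSON sidecar next to it.
#'
#' @param dataset A [cine_dataset()].
#' @param path Path to the `.tif` file; the sidecar is `path` with a
#'   `.json` extension appended.
#' @return `path`, invisibly.
#' @export
write_cine_tiff <- function(dataset, path) {
  stopifnot(inherits(dataset, "cine_dataset"))
  d <- dim(dataset$intensities)
  # TIFF samples live in [0, 1]; speckle can push intensities above 1, so
  # pages are stored divided by a scale recorded in the sidecar
  scale <- max(1, max(dataset$intensities))
  pages <- vector("list", d[1] * d[2])
  k <- 0
  for (ti in seq_len(d[1])) for (zi in seq_len(d[2])) {
    k <- k + 1
    pages[[k]] <- dataset$intensities[ti, zi, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  side <- list(
    intensity_scale = scale,
    n_frames = d[1], n_slices = d[2], image_size = c(d[3], d[4]),
    pixel_spacing_mm = dataset$pixel_spacing,
    slice_z_mm = dataset$slice_z,
    slice_spacing_mm = dataset$slice_spacing,
    cycle_phase = dataset$cycle_phase,
    apex_z = dataset$apex_z, base_z = dataset$base_z,
    cycle_duration_s = dataset$cycle_duration_s,
    animal_id = dataset$animal_id
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine_tiff
#' @export
read_cine_tiff <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) {
    abort(sprintf("missing sidecar '%s' for cine TIFF", side_path))
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- side$intensity_scale %||% 1
  arr <- array(0, dim = c(side$n_frames, side$n_slices,
                          side$image_size[1], side$image_size[2]))
  k <- 0
  for (ti in seq_len(side$n_frames)) for (zi in seq_len(side$n_slices)) {
    k <- k + 1
    arr[ti, zi, , ] <- pages[[k]] * scale
  }
  cine_dataset(arr, side$pixel_spacing_mm, side$slice_z_mm, side$cycle_phase,
               side$apex_z, side$base_z, side$animal_id, side$cycle_duration_s)
}

#' Write / read a cine dataset as a 4D NIfTI volume plus JSON sidecar
#'
#' Stores the stack as a NIfTI-1 volume ordered (x, y, z, t) with the
#' same JSON sidecar as the TIFF writer. Requires the RNifti package.
#'
#' @inheritParams write_cine_tiff
#' @export
write_cine_nifti <- function(dataset, path) {
  rlang::check_installed("RNifti")
  d <- dim(dataset$intensities)
  arr <- aperm(dataset$intensities, c(4, 3, 2, 1)) # (x, y, z, t)
  img <- RNifti::asNifti(arr, pixdim = c(dataset$pixel_spacing,
                                         dataset$pixel_spacing,
                                         dataset$slice_spacing,
                                         dataset$cycle_duration_s / d[1]))
  RNifti::writeNifti(img, path)
  side <- list(
    pixel_spacing_mm = dataset$pixel_spacing, slice_z_mm = dataset$slice_z,
    cycle_phase = dataset$cycle_phase, apex_z = dataset$apex_z,
    base_z = dataset$base_z, cycle_duration_s = dataset$cycle_duration_s,
    animal_id = dataset$animal_id
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path) {
  rlang::check_installed("RNifti")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- aperm(as.array(RNifti::readNifti(path)), c(4, 3, 2, 1))
  cine_dataset(arr, side$pixel_spacing_mm, side$slice_z_mm, side$cycle_phase,
               side$apex_z, side$base_z, side$animal_id, side$cycle_duration_s)
}

#' Anchor-radius CSV dialect
#'
#' Writes/reads anchor radii as plain CSV with columns `animal_id`,
#' `frame`, `phase`, `theta_deg`, `boundary`, `z_frac`, `radius_mm`
#' (shared by ground truth and model predictions).
#'
#' @param radii Tibble of anchor radii (with `animal_id`).
#' @param path CSV path.
#' @export
write_anchor_csv <- function(radii, path) {
  cols <- c("animal_id", "frame", "phase", "theta_deg", "boundary",
            "z_frac", "radius_mm")
  stopifnot(all(cols %in% names(radii)))
  readr::write_csv(radii[, cols], path)
  invisible(path)
}

#' @rdname write_anchor_csv
#' @export
read_anchor_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::mutate(anchor_id = sprintf("%s_z%03d_th%03d", .data$boundary,
                                      as.integer(round(.data$z_frac * 100)),
                                      as.integer(.data$theta_deg)))
}

#' Serialize / load a boundary model as a JSON container
#'
#' Coefficients, basis configuration and (optionally large) image-basis
#' arrays are stored in one JSON file with metadata.
#'
#' @param model A `boundary_model`.
#' @param path JSON path.
#' @export
write_boundary_model <- function(model, path) {
  stopifnot(inherits(model, "boundary_model"))
  obj <- list(
    format = "lvkin_boundary_model", version = 1L,
    variant = model$variant, k = model$k,
    n_basis = model$tbasis$n_basis, periodic = model$tbasis$periodic,
    assist_anchor = model$assist_anchor,
    coefficients = model$coefficients,
    coef_rownames = rownames(model$coefficients),
    image_bases = lapply(model$image_bases, function(b) {
      list(mean = b$mean, components = b$components, sdev = b$sdev,
           k = b$k, scope = b$scope, p = b$p)
    }),
    n_train_rows = model$n_train_rows, train_mse = model$train_mse
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_boundary_model
#' @export
read_boundary_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "lvkin_boundary_model")) {
    abort(sprintf("'%s' is not a boundary model container", path))
  }
  grid <- anchor_grid()
  co <- as.matrix(obj$coefficients)
  rownames(co) <- obj$coef_rownames
  colnames(co) <- grid$anchor_id
  bases <- if (is.data.frame(obj$image_bases)) {
    lapply(seq_len(nrow(obj$image_bases)), function(i) as.list(obj$image_bases[i, ]))
  } else obj$image_bases
  bases <- lapply(bases, function(b) {
    structure(list(mean = as.numeric(unlist(b$mean)),
                   components = as.matrix(if (is.list(b$components)) do.call(cbind, b$components) else b$components),
                   sdev = as.numeric(unlist(b$sdev)), k = b$k,
                   scope = b$scope, p = b$p),
              class = "image_basis")
  })
  structure(list(
    variant = obj$variant, k = obj$k,
    tbasis = time_basis(obj$n_basis, obj$periodic),
    image_bases = bases, coefficients = co,
    assist_anchor = obj$assist_anchor, anchor_grid = grid,
    n_train_rows = obj$n_train_rows, train_mse = obj$train_mse
  ), class = "boundary_model")
}

#' Export mesh surfaces as Wavefront OBJ files
#'
#' Writes one OBJ per (boundary, time sample) with quad faces joining
#' adjacent angle/z samples (closed around the angle axis).
#'
#' @param mesh An [build_lv_mesh()] result.
#' @param dir Output directory.
#' @param t_index Time samples to export (default: first only).
#' @return Paths written, invisibly.
#' @export
write_mesh_obj <- function(mesh, dir, t_index = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pts <- mesh_points(mesh)
  na <- length(mesh$angle_samples); nz <- length(mesh$z_samples)
  paths <- character(0)
  for (b in ANCHOR_BOUNDARIES) for (tt in t_index) {
    sub <- pts[pts$boundary == b & pts$t_index == tt, ]
    sub <- sub[order(sub$z_index, sub$angle_index), ]
    lines <- c(sprintf("# lvkin %s surface, time sample %d", b, tt),
               sprintf("v %.6f %.6f %.6f", sub$x_mm, sub$y_mm, sub$z_mm))
    vid <- function(a, z) (z - 1) * na + a
    faces <- character(0)
    for (z in seq_len(nz - 1)) for (a in seq_len(na)) {
      a2 <- if (a == na) 1L else a + 1L
      faces <- c(faces, sprintf("f %d %d %d %d", vid(a, z), vid(a2, z),
                                vid(a2, z + 1), vid(a, z + 1)))
    }
    p <- file.path(dir, sprintf("mesh_%s_t%02d.obj", b, tt))
    writeLines(c(lines, faces), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a mesh as a wide CSV point table
#'
#' @inheritParams write_mesh_obj
#' @param path CSV path.
#' @export
write_mesh_csv <- function(mesh, path) {
  readr::write_csv(mesh_points(mesh), path)
  invisible(path)
}
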