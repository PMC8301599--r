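# Allowed RunConfig keys, per block; unknown keys are rejected by name.
.config_schema <- list(
  phantom = c("n_animals", "frames_per_cycle", "image_size", "pixel_spacing",
              "n_slices_stored", "endo_radius_ed", "endo_radius_sd",
              "wall_thickness_ed", "contraction_fraction",
              "regional_amplitude_sd", "longitudinal_shortening", "ps_phase",
              "speckle_scale", "shadow", "heart_rate_bpm", "seed"),
  features = c("k_grid", "n_basis", "periodic"),
  models = c("variants", "k", "assist_anchor"),
  evaluation = c("n_iter", "seed", "alpha", "metric_alpha"),
  io = c("format")
)

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML or JSON with up to five blocks: `phantom`
#' (see [phantom_config()]), `features` (`k_grid`, `n_basis`,
#' `periodic`), `models` (`variants`, `k`, `assist_anchor`), `evaluation`
#' (`n_iter`, `seed`, `alpha`, `metric_alpha`) and `io` (`format`:
#' `tiff` or `nifti`). Any key outside this schema raises an error
#' naming the offending key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(raw)
}

#' @rdname read_run_config
#' @param config A raw configuration list.
#' @export
validate_run_config <- function(config) {
  bad_top <- setdiff(names(config), names(.config_schema))
  if (length(bad_top)) {
    abort(sprintf("unknown configuration block '%s'", bad_top[1]))
  }
  for (blk in names(config)) {
    bad <- setdiff(names(config[[blk]]), .config_schema[[blk]])
    if (length(bad)) {
      abort(sprintf("unknown key '%s' in configuration block '%s'", bad[1], blk))
    }
  }
  defaults <- list(
    phantom = list(n_animals = 8),
    features = list(k_grid = c(2, 4, 8), n_basis = 8, periodic = TRUE),
    models = list(variants = 1:3, k = 8, assist_anchor = "endo_z050_th090"),
    evaluation = list(n_iter = 20, seed = 1, alpha = 0.05, metric_alpha = 0.001),
    io = list(format = "tiff")
  )
  out <- defaults
  for (blk in names(config)) {
    out[[blk]] <- utils::modifyList(defaults[[blk]], as.list(config[[blk]]))
  }
  structure(out, class = "run_config")
}

.require_artifact <- function(path, stage_hint) {
  if (!file.exists(path)) {
    abort(sprintf("required artifact '%s' is missing; run the '%s' stage first",
                  path, stage_hint))
  }
  path
}

.write_manifest <- function(out_dir, stage, config, seed, inputs, outputs) {
  man <- list(
    stage = stage, config = unclass(config), seed = seed,
    package_version = as.character(utils::packageVersion("lvkin")),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(man, file.path(out_dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, digits = NA)
}

.load_cohort_artifacts <- function(out_dir) {
  truth_path <- .require_artifact(file.path(out_dir, "truth.csv"), "simulate")
  truth <- read_anchor_csv(truth_path)
  cine_dir <- .require_artifact(file.path(out_dir, "cine"), "simulate")
  files <- sort(list.files(cine_dir, pattern = "\\.(tif|nii(\\.gz)?)$",
                           full.names = TRUE))
  if (!length(files)) abort(sprintf("no cine files found under '%s'", cine_dir))
  datasets <- lapply(files, function(f) {
    if (grepl("\\.tif$", f)) read_cine_tiff(f) else read_cine_nifti(f)
  })
  ids <- vapply(datasets, function(d) d$animal_id, character(1))
  tibble(
    animal_id = ids,
    dataset = datasets,
    truth = lapply(ids, function(a) {
      dplyr::select(truth[truth$animal_id == a, ], -"animal_id")
    })
  )
}

#' Run one pipeline stage
#'
#' Ties the modules into a staged file-based pipeline: `simulate` writes
#' the phantom cohort (cine stacks plus ground-truth radii), `fit` trains
#' the configured model variants on the whole cohort, `predict` writes
#' per-variant predicted anchor radii, `evaluate` runs the Monte Carlo
#' cross-validation, and `metrics` builds ground-truth and predicted
#' meshes, derives kinematic metric tables and compares them. Every
#' stage writes a manifest with the configuration, seed and MD5
#' checksums of its inputs and outputs; given identical configuration a
#' rerun reproduces its outputs byte for byte.
#'
#' @param config A `run_config` (see [read_run_config()]), or a raw list
#'   which is validated first.
#' @param stage One of `"simulate"`, `"fit"`, `"predict"`, `"evaluate"`,
#'   `"metrics"`.
#' @param out_dir Artifact directory (created if needed).
#' @param seed Optional override of the configured seeds.
#' @return Invisibly, a character vector of artifact paths written.
#' @export
run_pipeline <- function(config, stage, out_dir, seed = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  stage <- match.arg(stage, c("simulate", "fit", "predict", "evaluate", "metrics"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) {
    config$phantom$seed <- as.integer(seed)
    config$evaluation$seed <- as.integer(seed)
  }
  tb <- time_basis(config$features$n_basis, config$features$periodic)
  written <- character(0)

  if (stage == "simulate") {
    pc <- do.call(phantom_config, config$phantom)
    cohort <- generate_cohort(pc)
    cine_dir <- file.path(out_dir, "cine")
    dir.create(cine_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort))) {
      ds <- cohort$dataset[[i]]
      p <- if (config$io$format == "nifti") {
        write_cine_nifti(ds, file.path(cine_dir, paste0(ds$animal_id, ".nii")))
      } else {
        write_cine_tiff(ds, file.path(cine_dir, paste0(ds$animal_id, ".tif")))
      }
      written <- c(written, p, paste0(p, ".json"))
    }
    tp <- file.path(out_dir, "truth.csv")
    write_anchor_csv(cohort_truth(cohort), tp)
    written <- c(written, tp)
    .write_manifest(out_dir, stage, config, config$phantom$seed,
                    character(0), written)
  } else if (stage == "fit") {
    cohort <- .load_cohort_artifacts(out_dir)
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    for (v in config$models$variants) {
      m <- fit_boundary_model(cohort, v, config$models$k, tb,
                              assist_anchor = config$models$assist_anchor)
      p <- file.path(out_dir, "models", sprintf("model_variant%d.json", v))
      write_boundary_model(m, p)
      written <- c(written, p)
    }
    .write_manifest(out_dir, stage, config, NULL,
                    file.path(out_dir, "truth.csv"), written)
  } else if (stage == "predict") {
    cohort <- .load_cohort_artifacts(out_dir)
    grid <- anchor_grid()
    for (v in config$models$variants) {
      mp <- .require_artifact(
        file.path(out_dir, "models", sprintf("model_variant%d.json", v)), "fit")
      m <- read_boundary_model(mp)
      preds <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
        assist <- NULL
        if (v == 3) {
          tr <- cohort$truth[[i]]
          assist <- tr$radius_mm[tr$anchor_id == m$assist_anchor & tr$frame == 1]
        }
        predict_radii(m, cohort$dataset[[i]], assist) |>
          dplyr::mutate(animal_id = cohort$animal_id[i])
      })
      p <- file.path(out_dir, sprintf("predictions_variant%d.csv", v))
      write_anchor_csv(preds, p)
      written <- c(written, p)
    }
    .write_manifest(out_dir, stage, config, NULL,
                    file.path(out_dir, "truth.csv"), written)
  } else if (stage == "evaluate") {
    cohort <- .load_cohort_artifacts(out_dir)
    cv <- run_cross_validation(
      cohort, variants = config$models$variants,
      n_iter = config$evaluation$n_iter, k_grid = config$features$k_grid,
      tbasis = tb, assist_anchor = config$models$assist_anchor,
      seed = config$evaluation$seed
    )
    pj <- file.path(out_dir, "cv_result.json")
    jsonlite::write_json(
      list(summary = cv$summary, percent_significant = cv$percent_significant,
           selected_k = cv$selected_k, anchors = cv$anchors,
           n_iter = cv$n_iter, k_grid = cv$k_grid, seed = cv$seed),
      pj, auto_unbox = TRUE, digits = NA
    )
    pa <- file.path(out_dir, "cv_anchors.csv")
    readr::write_csv(cv$anchors, pa)
    written <- c(written, pj, pa)
    for (v in cv$variants) for (b in ANCHOR_BOUNDARIES) {
      hm <- cv$heatmap[cv$heatmap$variant == v & cv$heatmap$boundary == b, ]
      wide <- tidyr::pivot_wider(
        dplyr::select(hm, "theta_deg", "z_frac", "median_mse"),
        names_from = "z_frac", values_from = "median_mse", names_prefix = "z")
      p <- file.path(out_dir, sprintf("heatmap_mse_%s_m%d.csv", b, v))
      readr::write_csv(wide, p)
      written <- c(written, p)
    }
    .write_manifest(out_dir, stage, config, config$evaluation$seed,
                    file.path(out_dir, "truth.csv"), written)
  } else if (stage == "metrics") {
    cohort <- .load_cohort_artifacts(out_dir)
    truth_tabs <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      ds <- cohort$dataset[[i]]
      mesh <- build_lv_mesh(cohort$truth[[i]], ds$apex_z, ds$base_z,
                            ds$cycle_duration_s)
      dplyr::mutate(metric_table(mesh), id = cohort$animal_id[i])
    })
    pt <- file.path(out_dir, "metrics_truth.csv")
    readr::write_csv(truth_tabs, pt)
    written <- c(written, pt)
    for (v in config$models$variants) {
      pp <- .require_artifact(
        file.path(out_dir, sprintf("predictions_variant%d.csv", v)), "predict")
      preds <- read_anchor_csv(pp)
      pred_tabs <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
        ds <- cohort$dataset[[i]]
        pr <- preds[preds$animal_id == cohort$animal_id[i], ]
        pr$radius_mm <- pmax(pr$radius_mm, 0.05) # guard degenerate predictions
        mesh <- build_lv_mesh(pr, ds$apex_z, ds$base_z, ds$cycle_duration_s)
        dplyr::mutate(metric_table(mesh), id = cohort$animal_id[i])
      })
      pm <- file.path(out_dir, sprintf("metrics_variant%d.csv", v))
      readr::write_csv(pred_tabs, pm)
      comp <- compare_metric_tables(truth_tabs, pred_tabs,
                                    alpha = config$evaluation$metric_alpha)
      pc2 <- file.path(out_dir, sprintf("metric_comparison_variant%d.csv", v))
      readr::write_csv(comp, pc2)
      written <- c(written, pm, pc2)
    }
    .write_manifest(out_dir, stage, config, NULL,
                    file.path(out_dir, "truth.csv"), written)
  }
  invisible(written)
}
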