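# End-to-end pipelines tying the stages together, with run manifests
# recording every threshold actually used so a run can be reproduced.

run_manifest <- function(seed, configs, inputs = character(), outputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  list(
    package = "resolvequant",
    version = as.character(utils::packageVersion("resolvequant")),
    seed = seed,
    config = lapply(configs, unclass),
    input_digests = digests,
    outputs = as.list(outputs)
  )
}

#' Run the full IHC quantification pipeline
#'
#' Composes tissue identification, ROI selection, stain detection and
#' cell quantification into one call:
#' `identify_tissue()` -> `select_rois()` -> `stain_maps()` ->
#' `detect_nuclei()` -> `grow_cell_bodies()` -> `classify_cells()` ->
#' `density_report()`. With `out_dir` set, the cell table, per-ROI report
#' and a JSON manifest of every threshold used are written; outputs are
#' deterministic, so re-running an identical manifest reproduces
#' byte-identical CSVs.
#'
#' @param slide a `slide` object, an RGB array, or a TIFF path readable
#'   by [read_slide()] (pixel-size sidecar required).
#' @param tissue_cfg,stain_cfg,cell_cfg stage configurations.
#' @param n_rois ROIs for the automatic grid (4).
#' @param roi_labels optional user ROI label raster.
#' @param pixel_size_um required if `slide` carries no metadata.
#' @param out_dir optional output directory.
#' @return list with `report` (a `density_report`, or NULL for a slide
#'   with no tissue), `cells`, `tissue`, `maps`, `nuclei`, `bodies`,
#'   `manifest`.
#' @export
run_ihc_pipeline <- function(slide,
                             tissue_cfg = tissue_config(),
                             stain_cfg = stain_config(),
                             cell_cfg = cell_config(),
                             n_rois = 4L, roi_labels = NULL,
                             pixel_size_um = NULL, out_dir = NULL) {
  input_path <- character()
  if (is.character(slide)) {
    input_path <- slide
    slide <- read_slide(slide)
  }
  if (inherits(slide, "slide")) {
    pixel_size_um <- pixel_size_um %||% slide$pixel_size_um
  } else {
    slide <- structure(list(rgb = slide, pixel_size_um = pixel_size_um),
                       class = "slide")
  }
  if (is.null(pixel_size_um)) {
    rlang::abort("pixel_size_um missing: supply it or a slide sidecar (pixel_size_um)",
                 class = "resolvequant_data_error")
  }

  tissue <- identify_tissue(slide, tissue_cfg, pixel_size_um)
  if (!any(tissue$mask)) {
    rlang::warn("no tissue identified: empty report")
    manifest <- run_manifest(NA, list(tissue = tissue_cfg, stain = stain_cfg,
                                      cell = cell_cfg), input_path)
    return(list(report = NULL,
                cells = classify_cells(matrix(0L, 1, 1), matrix(0L, 1, 1),
                                       matrix(0, 1, 1), cell_cfg),
                tissue = tissue, maps = NULL, nuclei = NULL, bodies = NULL,
                manifest = manifest))
  }
  rois <- select_rois(tissue$mask, n_rois, roi_labels)
  maps <- stain_maps(slide, stain_cfg)
  nuclei <- detect_nuclei(maps$normalized_blue, tissue$mask, cell_cfg,
                          pixel_size_um)
  bodies <- grow_cell_bodies(nuclei, tissue$mask, cell_cfg, pixel_size_um)
  cells <- classify_cells(nuclei, bodies, maps$brown_positive, cell_cfg)
  report <- density_report(cells, rois, tissue$mask, pixel_size_um)

  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cell_path <- file.path(out_dir, "cells.csv")
    report_path <- file.path(out_dir, "density_report.csv")
    readr::write_csv(cells, cell_path)
    readr::write_csv(tidy(report), report_path)
    outputs <- c(cell_path, report_path)
  }
  manifest <- run_manifest(NA, list(tissue = tissue_cfg, stain = stain_cfg,
                                    cell = cell_cfg),
                           inputs = input_path, outputs = outputs)
  manifest$thresholds_used <- as.list(tissue$thresholds)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, cells = cells, tissue = tissue, maps = maps,
       nuclei = nuclei, bodies = bodies, manifest = manifest)
}

#' Run the lipid-mediator profiling pipeline
#'
#' Composes identification, quantification, PLS-DA and temporal testing
#' over a long concentration table (or a feature table plus standards
#' library). PLS-DA is refused with a clear message when fewer than two
#' time points are present; temporal tests are skipped in that case.
#'
#' @param table long tibble `donor`, `time_h`, `mediator`,
#'   `concentration_pg`, or a CSV path.
#' @param reference_time baseline for the temporal tests (0 h).
#' @param scale PLS-DA scaling (see [plsda()]).
#' @param p_adjust post-hoc correction (see [temporal_test()]).
#' @param out_dir optional output directory for scores/loadings/test CSVs
#'   and the manifest.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return list with `plsda` (or NULL), `tests` (or NULL), `table`,
#'   `manifest`.
#' @export
run_lm_pipeline <- function(table, reference_time = 0, scale = "unit",
                            p_adjust = "holm", out_dir = NULL, seed = NA) {
  input_path <- character()
  if (is.character(table)) {
    input_path <- table
    table <- readr::read_csv(table, show_col_types = FALSE)
  }
  required <- c("donor", "time_h", "mediator", "concentration_pg")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols)) {
    rlang::abort(paste0("table is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "resolvequant_data_error")
  }

  n_times <- length(unique(table$time_h))
  fit <- NULL
  tests <- NULL
  if (n_times < 2) {
    rlang::warn("only one time point: PLS-DA refused, temporal tests skipped")
  } else {
    wide <- exudate_wide(table)
    fit <- plsda(wide$x, wide$group, n_components = 2, scale = scale)
    tests <- temporal_test_all(table, reference_time, p_adjust)
  }

  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(fit)) {
      sp <- file.path(out_dir, "plsda_scores.csv")
      lp <- file.path(out_dir, "plsda_loadings.csv")
      readr::write_csv(tidy(fit, "scores"), sp)
      readr::write_csv(tidy(fit, "loadings"), lp)
      outputs <- c(outputs, sp, lp)
    }
    if (!is.null(tests)) {
      tp <- file.path(out_dir, "temporal_tests.csv")
      readr::write_csv(tests, tp)
      outputs <- c(outputs, tp)
    }
  }
  manifest <- run_manifest(seed,
                           list(reference_time = reference_time,
                                scale = scale, p_adjust = p_adjust),
                           inputs = input_path, outputs = outputs)
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(plsda = fit, tests = tests, table = table, manifest = manifest)
}
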