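# Pipeline orchestration: a single config drives simulate -> correct ->
# segment -> gate -> report (-> qpcr), with a manifest recording parameters,
# seeds, the config hash and per-stage record counts.

#' Build a pipeline run configuration
#'
#' @param layout A [plate_layout()], or `NULL` to read `layout.tsv` from
#'   `image_dir`.
#' @param image_dir Directory of raw TIFF images (as written by
#'   [simulate_plate()]); `NULL` when the `simulate` stage renders in memory.
#' @param out_dir Output directory for tables and the manifest; `NULL`
#'   disables writing.
#' @param stages Character subset of
#'   `c("simulate", "correct", "segment", "gate", "report", "qpcr")` in
#'   pipeline order; later stages require earlier ones' outputs.
#' @param params [synth_params()] for the simulate stage.
#' @param effect_table Condition effects for the simulate stage (see
#'   [sample_nuclei()]).
#' @param design Crosstalk design tibble (`channel`, `canonical`) for the
#'   report stage.
#' @param control Control condition label.
#' @param alpha Per-comparison significance level.
#' @param min_area,max_area Segmentation size limits (pixels).
#' @param smooth_sigma Shading-smoothing SD (pixels); `NULL` for the default.
#' @param per_well Fit the DNA-content mixture per well (default) or pooled.
#' @param ct_table qPCR Ct table (see [analyze_qpcr()]) or `NULL`.
#' @param qpcr_target,qpcr_reference Gene labels for the qPCR stage.
#' @param seed Master seed; per-stage sub-seeds are derived by fixed offsets.
#' @return A `run_config` list.
#' @export
run_config <- function(layout = NULL, image_dir = NULL, out_dir = NULL,
                       stages = c("simulate", "correct", "segment",
                                  "gate", "report"),
                       params = synth_params(), effect_table = NULL,
                       design = NULL, control = "control", alpha = 0.05,
                       min_area = 10L, max_area = 600L, smooth_sigma = NULL,
                       per_well = TRUE, ct_table = NULL,
                       qpcr_target = "target", qpcr_reference = "18S",
                       seed = 1L) {
  all_stages <- c("simulate", "correct", "segment", "gate", "report", "qpcr")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "platetalk_config_error")
  }
  if (is.null(layout) && is.null(image_dir)) {
    abort("either a layout or an image directory is required",
          class = "platetalk_config_error")
  }
  cfg <- list(layout = layout, image_dir = image_dir, out_dir = out_dir,
              stages = all_stages[all_stages %in% stages],
              params = params, effect_table = effect_table, design = design,
              control = control, alpha = alpha,
              min_area = min_area, max_area = max_area,
              smooth_sigma = smooth_sigma, per_well = per_well,
              ct_table = ct_table, qpcr_target = qpcr_target,
              qpcr_reference = qpcr_reference, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a plate's raw images from a directory
#'
#' Expects the [simulate_plate()] naming scheme
#' `<well>_f<NN>_<channel>.tif` plus `layout.tsv`.
#'
#' @param dir Image directory.
#' @param layout Optional [plate_layout()]; read from the directory if
#'   omitted.
#' @return A list with `layout` and `images` (tibble as in [render_plate()]).
#' @export
read_plate_images <- function(dir, layout = NULL) {
  layout <- layout %||% read_plate_layout(file.path(dir, "layout.tsv"))
  grid <- tidyr::expand_grid(
    layout$wells[, c("well_id", "role")],
    field = seq_len(layout$fields_per_well),
    channel = layout$channels
  )
  paths <- file.path(dir, image_filename(grid$well_id, grid$field, grid$channel))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing image file(s), e.g. ", basename(missing[1])),
          class = "platetalk_missing_input")
  }
  grid$image <- map(paths, read_field_tiff)
  list(layout = layout, images = grid)
}

#' Run the pipeline
#'
#' Executes the configured stages in order and (when `out_dir` is set) writes
#' each stage's table as CSV plus a JSON manifest carrying the package
#' version, seed, config hash and per-stage record counts.  A stage failure
#' aborts with the failing stage named; tables written before the failure are
#' retained.
#'
#' @param config A [run_config()].
#' @return A list with the produced artefacts: `layout`, `truth` (simulate
#'   only), `corrected`, `nuclei`, `gated`, `gate_report`, `medians`,
#'   `responses`, `crosstalk`, `qpcr`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg_hash <- rlang::hash(unclass(config))
  out <- list(manifest = list(
    package = "platetalk",
    version = as.character(utils::packageVersion("platetalk")),
    seed = config$seed, config_hash = cfg_hash,
    stages = config$stages, counts = list()
  ))
  run_stage <- function(stage, expr) {
    inform(paste0("[platetalk] stage: ", stage))
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            class = "platetalk_stage_failure", parent = e)
    })
  }
  want <- function(s) s %in% config$stages
  layout <- config$layout
  images <- NULL

  if (want("simulate")) {
    sim <- run_stage("simulate", simulate_plate(
      layout, config$effect_table, config$params,
      seed = stage_seed(config$seed, "simulate"), dir = config$image_dir))
    out$truth <- sim$truth
    images <- sim$images
    out$manifest$counts$simulated_nuclei <- nrow(sim$truth$nuclei)
  } else if (!is.null(config$image_dir)) {
    loaded <- run_stage("load", read_plate_images(config$image_dir, layout))
    layout <- loaded$layout
    images <- loaded$images
  }
  out$layout <- layout

  if (want("correct")) {
    out$corrected <- run_stage("correct", correct_plate(
      images, smooth_sigma = config$smooth_sigma))
    out$manifest$counts$corrected_images <- nrow(out$corrected)
  }
  if (want("segment")) {
    out$nuclei <- run_stage("segment", quantify_plate(
      out$corrected, hoechst_channel = hoechst_channel(layout),
      min_area = config$min_area, max_area = config$max_area))
    out$manifest$counts$segmented_nuclei <- nrow(out$nuclei)
  }
  if (want("gate")) {
    g <- run_stage("gate", gate_cells(
      out$nuclei, hoechst_channel = hoechst_channel(layout),
      per_well = config$per_well, seed = stage_seed(config$seed, "gate")))
    out$gated <- g$records
    out$gate_report <- g$report
    out$manifest$counts$gated_nuclei <- nrow(g$records)
  }
  if (want("report")) {
    design <- config$design
    if (is.null(design)) {
      abort("stage 'report' needs a crosstalk design (channel, canonical)",
            class = "platetalk_config_error")
    }
    out$medians <- run_stage("report", summarize_conditions(out$gated, layout))
    normalized <- run_stage("report", normalize_conditions(
      out$medians, config$control, setNames(design$canonical, design$channel)))
    out$responses <- condition_response(normalized)
    out$crosstalk <- run_stage("report", build_crosstalk_matrix(
      out$medians, design, control = config$control, alpha = config$alpha))
    out$manifest$counts$crosstalk_calls <- nrow(out$crosstalk)
  }
  if (want("qpcr")) {
    if (is.null(config$ct_table)) {
      abort("stage 'qpcr' needs a Ct table", class = "platetalk_config_error")
    }
    out$qpcr <- run_stage("qpcr", analyze_qpcr(
      config$ct_table, config$qpcr_target, config$qpcr_reference,
      control = config$control, alpha = config$alpha))
    out$manifest$counts$qpcr_tests <- nrow(out$qpcr$tests)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) {
      df$config_hash <- cfg_hash
      df
    }
    save_tbl <- function(df, name) {
      if (!is.null(df)) utils::write.csv(stamp(df),
                                         file.path(config$out_dir,
                                                   paste0(name, ".csv")),
                                         row.names = FALSE)
    }
    save_tbl(out$nuclei, "nuclei")
    save_tbl(out$gated, "gated_nuclei")
    save_tbl(out$gate_report, "gate_report")
    save_tbl(out$medians, "condition_medians")
    save_tbl(out$responses, "condition_responses")
    save_tbl(out$crosstalk, "crosstalk_calls")
    if (!is.null(out$crosstalk)) {
      format_crosstalk_report(out$crosstalk, alpha = config$alpha,
                              path = file.path(config$out_dir,
                                               "crosstalk_report.txt"))
    }
    if (!is.null(out$qpcr)) save_tbl(out$qpcr$tests, "qpcr_tests")
    jsonlite::write_json(out$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
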