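#' Read and write electropherogram CSV files
#'
#' The on-disk dialect is a two-column CSV `time_min,signal_mau` with a
#' header row, one file per run, plus an optional JSON metadata sidecar with
#' the same basename and extension `.meta.json`.
#'
#' @param eg An `electropherogram`.
#' @param path CSV file path.
#' @param write_meta Write the metadata sidecar (default `TRUE`).
#' @return `write_electropherogram()` returns `path` invisibly;
#'   `read_electropherogram()` returns an `electropherogram`.
#' @export
write_electropherogram <- function(eg, path, write_meta = TRUE) {
  eg <- as_electropherogram_df(eg)
  readr::write_csv(tibble(time_min = eg$time_min, signal_mau = eg$signal_mau),
                   path)
  meta <- attr(eg, "metadata")
  if (write_meta && length(meta)) {
    jsonlite::write_json(meta, meta_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_electropherogram
#' @export
read_electropherogram <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    time_min = readr::col_double(), signal_mau = readr::col_double()
  ))
  meta <- list()
  mp <- meta_path(path)
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  new_electropherogram(d$time_min, d$signal_mau, metadata = meta)
}

meta_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' Write a study to disk with its manifest
#'
#' Writes one electropherogram CSV per run and a manifest CSV
#' `run_id,sample_label,nominal_conc_ug_ml,file`.
#'
#' @param study A study tibble with `run_id`, `nominal_conc_ug_ml` and an
#'   `eg` list-column.
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(is.data.frame(study), all(c("run_id", "eg") %in% names(study)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s.csv", study$run_id)
  purrr::walk2(study$eg, file.path(dir, files), write_electropherogram)
  manifest <- tibble(
    run_id = study$run_id,
    sample_label = study$run_id,
    nominal_conc_ug_ml = study$nominal_conc_ug_ml,
    file = files
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a study back from a manifest
#'
#' @param dir Directory containing `manifest.csv` and the run CSVs.
#' @return A study tibble with an `eg` list-column.
#' @export
read_study <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv found in `%s`.", dir))
  manifest <- readr::read_csv(mf, col_types = readr::cols())
  manifest |>
    dplyr::mutate(eg = purrr::map(file.path(dir, .data$file),
                                  read_electropherogram))
}

# pipeline configuration ------------------------------------------------------

#' Pipeline configuration for a full validation
#'
#' Bundles the simulation conditions with the analysis thresholds and the
#' robustness ground-truth specification consumed by
#' [run_full_validation()].
#'
#' @param simulation A [sim_config()] or a named list of its arguments.
#' @param rsd_limit SST RSD acceptance limit (%, default 2).
#' @param alpha Significance level for the linearity ANOVA (default 0.05).
#' @param sst_n Number of system-suitability replicate runs (default 10).
#' @param repeatability_n Number of repeatability determinations (default 7).
#' @param precision_days Number of days for intermediate precision
#'   (default 3).
#' @param recovery_added Standard concentrations added in the spike-recovery
#'   study (micrograms/mL; defaults 10, 30, 50 over a 70 base, i.e. the 80,
#'   100 and 120% levels).
#' @param recovery_base Unspiked formulation concentration (micrograms/mL).
#' @param factor_effects Per-factor true content shifts for the robustness
#'   simulation (default all zero: a robust method).
#' @param robustness_noise_sd Assay noise on robustness run contents (%).
#' @return A list of class `pipeline_config`.
#' @export
validation_config <- function(simulation = sim_config(),
                              rsd_limit = 2,
                              alpha = 0.05,
                              sst_n = 10,
                              repeatability_n = 7,
                              precision_days = 3,
                              recovery_added = c(10, 30, 50),
                              recovery_base = 70,
                              factor_effects = rep(0, 7),
                              robustness_noise_sd = 0.3) {
  if (is.list(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  stopifnot(inherits(simulation, "sim_config"))
  check_number(rsd_limit, "rsd_limit", min = 0, strict_min = TRUE)
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  check_number(sst_n, "sst_n", min = 2)
  check_number(repeatability_n, "repeatability_n", min = 2)
  check_number(precision_days, "precision_days", min = 2)
  check_number(recovery_base, "recovery_base", min = 0, strict_min = TRUE)
  if (any(recovery_added <= 0)) abort("`recovery_added` must be > 0.")
  structure(
    list(
      simulation = simulation,
      rsd_limit = rsd_limit, alpha = alpha,
      sst_n = as.integer(sst_n),
      repeatability_n = as.integer(repeatability_n),
      precision_days = as.integer(precision_days),
      recovery_added = recovery_added,
      recovery_base = recovery_base,
      factor_effects = factor_effects,
      robustness_noise_sd = robustness_noise_sd
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the argument names of [validation_config()], with the
#' simulation parameters nested under `simulation:` mirroring [sim_config()].
#' Unknown keys are rejected so typos fail loudly instead of silently using
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_validation_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- setdiff(names(formals(validation_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$simulation)) {
    sim_allowed <- names(formals(sim_config))
    sim_unknown <- setdiff(names(raw$simulation), sim_allowed)
    if (length(sim_unknown)) {
      abort(sprintf("Unknown simulation key(s): %s",
                    paste(sim_unknown, collapse = ", ")))
    }
    if (!is.null(raw$simulation$calibration_levels)) {
      raw$simulation$calibration_levels <-
        unlist(raw$simulation$calibration_levels)
    }
  }
  if (!is.null(raw$factor_effects)) {
    raw$factor_effects <- unlist(raw$factor_effects)
  }
  if (!is.null(raw$recovery_added)) raw$recovery_added <- unlist(raw$recovery_added)
  do.call(validation_config, raw)
}
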