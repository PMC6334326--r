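#' Run the full validation pipeline
#'
#' Executes every stage end to end on simulated data with known ground
#' truth: calibration study -> peak metrology -> linearity fit and
#' lack-of-fit ANOVA -> LOD/LOQ; system-suitability study -> SST summary;
#' content, repeatability, intermediate precision and spike recovery by
#' external-standard assay; and the Plackett-Burman robustness screen with
#' the Youden-Steiner assessment. All randomness descends deterministically
#' from `seed`, so the same configuration and seed reproduce the report
#' bit for bit.
#'
#' @param config A [validation_config()].
#' @param seed Integer master seed (defaults to the simulation config seed).
#' @param outdir If non-`NULL`, stage CSVs and the JSON/plain-text report are
#'   written there via [write_validation_report()].
#' @return An object of class `validation_report`; see
#'   [write_validation_report()] for the serialised layout.
#' @examples
#' \donttest{
#' rep <- run_full_validation(validation_config(), seed = 42)
#' print(rep)
#' }
#' @export
run_full_validation <- function(config = validation_config(),
                                seed = config$simulation$seed,
                                outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  check_number(seed, "seed")
  sim <- config$simulation

  seeded <- function(base, i = 0) derive_seed(seed, base + i)
  sim_at <- function(conc, sd, label) {
    simulate_electropherogram(sim, conc, seed = sd, label = label)
  }
  measure_area <- function(eg) process_electropherogram(eg)$corrected_area

  # -- calibration, linearity, LOD/LOQ ---------------------------------------
  cal_sim <- sim
  cal_sim$seed <- as.integer(seeded(1) %% 2147483647)
  cal_study <- simulate_calibration_study(cal_sim)
  cal_peaks <- process_study(cal_study)
  cal_data <- tibble(
    concentration = cal_peaks$nominal_conc_ug_ml,
    corrected_area = cal_peaks$corrected_area
  )
  fit <- fit_calibration(cal_data)
  anova_tab <- linearity_anova(cal_data, alpha = config$alpha)
  limits <- lod_loq_from_fit(fit)

  # -- system suitability ----------------------------------------------------
  sst_sim <- sim
  sst_sim$seed <- as.integer(seeded(2) %% 2147483647)
  sst_study <- simulate_sst_study(sst_sim, n = config$sst_n)
  sst_peaks <- process_study(sst_study)
  sst_tab <- sst_summary(sst_peaks, rsd_limit = config$rsd_limit)

  # -- content (triplicate sample vs reference standard at 100 ug/mL) --------
  content_one <- function(base, i) {
    a_s <- measure_area(sim_at(100, seeded(base, 2 * i - 1), "sample"))
    a_rs <- measure_area(sim_at(100, seeded(base, 2 * i), "reference"))
    assay_content(a_s, a_rs, c_rs = 100, c_t = 100)$cs_percent
  }
  content_reps <- vapply(1:3, function(i) content_one(20000, i), numeric(1))
  content_rsd <- rsd(content_reps)

  # -- repeatability: 7 determinations against one reference -----------------
  a_rs_rep <- measure_area(sim_at(100, seeded(30000), "reference"))
  repeat_contents <- vapply(seq_len(config$repeatability_n), function(i) {
    a_s <- measure_area(sim_at(100, seeded(30000, i), "sample"))
    assay_content(a_s, a_rs_rep, 100, 100)$cs_percent
  }, numeric(1))
  repeatability <- rsd(repeat_contents)

  # -- intermediate precision: triplicate content on separate days -----------
  day_means <- vapply(seq_len(config$precision_days), function(day) {
    mean(vapply(1:3, function(i) content_one(40000 + 100 * day, i),
                numeric(1)))
  }, numeric(1))
  ip <- intermediate_precision(day_means)

  # -- accuracy / spike recovery ---------------------------------------------
  conc_from_area <- function(a) (a - fit$intercept) / fit$slope
  cu_meas <- mean(vapply(1:3, function(i) {
    conc_from_area(measure_area(sim_at(config$recovery_base,
                                       seeded(50000, i), "unspiked")))
  }, numeric(1)))
  rec_tab <- tidyr::expand_grid(
    added = config$recovery_added, replicate = 1:3
  ) |>
    dplyr::mutate(
      cf_measured = purrr::map2_dbl(.data$added, dplyr::row_number(),
        function(ca, i) {
          conc_from_area(measure_area(
            sim_at(config$recovery_base + ca, seeded(51000, i), "spiked")
          ))
        }),
      r_percent = recovery(.data$cf_measured, cu_meas, .data$added)$r_percent
    )
  rec_rsd <- rsd(rec_tab$r_percent)

  # -- robustness -------------------------------------------------------------
  design <- pb_design()
  rob_runs <- simulate_robustness_study(
    design, config$factor_effects,
    noise_sd = config$robustness_noise_sd, seed = seeded(60000)
  )
  rob <- assess_robustness(pb_effects(design, rob_runs))

  report <- structure(
    list(
      content = list(percent = content_rsd$mean,
                     rsd_percent = content_rsd$rsd_percent,
                     replicates = content_reps),
      linearity = list(
        equation = sprintf("y = %.6g x %+.6g", fit$slope, fit$intercept),
        slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, residual_sd = fit$residual_sd,
        range_ug_ml = range(sim$calibration_levels),
        anova = anova_tab
      ),
      repeatability = repeatability,
      intermediate_precision = list(day_means = day_means, summary = ip),
      accuracy = list(mean_recovery = rec_rsd$mean,
                      rsd_percent = rec_rsd$rsd_percent,
                      table = rec_tab),
      lod = limits$lod, loq = limits$loq,
      sst = sst_tab,
      robustness = rob,
      provenance = list(
        schema_version = "1.0",
        seed = as.integer(seed),
        config_hash = rlang::hash(config),
        timestamp = format(Sys.time(), tz = "UTC")
      )
    ),
    class = "validation_report"
  )
  if (!is.null(outdir)) write_validation_report(report, outdir)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2)
  cat("== CE method validation report ==\n")
  cat(sprintf("%-28s %s%%  (RSD %s%%)\n", "Content", fmt(x$content$percent),
              fmt(x$content$rsd_percent)))
  cat(sprintf("%-28s %s, R^2 = %.4f (%g to %g ug/mL)\n", "Linearity",
              x$linearity$equation, x$linearity$r_squared,
              x$linearity$range_ug_ml[1], x$linearity$range_ug_ml[2]))
  cat(sprintf("%-28s RSD = %s%% (n = %d)\n", "Repeatability",
              fmt(x$repeatability$rsd_percent), x$repeatability$n))
  cat(sprintf("%-28s %s - RSD = %s%%\n", "Intermediate precision",
              paste(sprintf("day %d: %s%%",
                            seq_along(x$intermediate_precision$day_means),
                            fmt(x$intermediate_precision$day_means)),
                    collapse = "; "),
              fmt(x$intermediate_precision$summary$rsd_percent)))
  cat(sprintf("%-28s %s%%, RSD = %s%%\n", "Accuracy (recovery)",
              fmt(x$accuracy$mean_recovery), fmt(x$accuracy$rsd_percent)))
  cat(sprintf("%-28s %s ug/mL\n", "LOD", fmt(x$lod)))
  cat(sprintf("%-28s %s ug/mL\n", "LOQ", fmt(x$loq)))
  cat(sprintf("%-28s %s\n", "SST",
              if (all(x$sst$pass)) "all metrics pass" else "FAILURES"))
  cat(sprintf("%-28s %s\n", "Robustness",
              if (x$robustness$overall_robust) "robust (all factors)"
              else "NOT robust"))
  invisible(x)
}

# JSON-serialisable form of the report (numbers kept at full precision)
report_json <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  list(
    schema_version = report$provenance$schema_version,
    content = report$content,
    linearity = list(
      equation = report$linearity$equation,
      slope = report$linearity$slope,
      intercept = report$linearity$intercept,
      r_squared = report$linearity$r_squared,
      residual_sd = report$linearity$residual_sd,
      range_ug_ml = report$linearity$range_ug_ml,
      anova = as.data.frame(tidy(report$linearity$anova))
    ),
    repeatability = as.data.frame(report$repeatability),
    intermediate_precision = list(
      day_means = report$intermediate_precision$day_means,
      summary = as.data.frame(report$intermediate_precision$summary)
    ),
    accuracy = list(
      mean_recovery = report$accuracy$mean_recovery,
      rsd_percent = report$accuracy$rsd_percent,
      table = as.data.frame(report$accuracy$table)
    ),
    lod = report$lod, loq = report$loq,
    sst = as.data.frame(report$sst),
    robustness = list(
      table = as.data.frame(tidy(report$robustness)),
      overall_robust = report$robustness$overall_robust
    ),
    provenance = report$provenance
  )
}

#' Serialise a validation report
#'
#' Writes the stage CSVs (`linearity.csv`, `content.csv`, `recovery.csv`,
#' `sst.csv`, `robustness.csv`), the fitted line (`fit.json`), the complete
#' machine-readable report (`report.json`, schema-versioned, lossless for
#' all numeric fields), and a human-readable `report.txt` mirroring the
#' parameter/result layout of a validation summary table.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report$linearity$anova),
                   file.path(dir, "linearity.csv"))
  jsonlite::write_json(
    list(slope = report$linearity$slope,
         intercept = report$linearity$intercept,
         r_squared = report$linearity$r_squared,
         residual_sd = report$linearity$residual_sd),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(
    tibble(replicate = seq_along(report$content$replicates),
           content_percent = report$content$replicates),
    file.path(dir, "content.csv")
  )
  readr::write_csv(report$accuracy$table, file.path(dir, "recovery.csv"))
  readr::write_csv(report$sst, file.path(dir, "sst.csv"))
  rob <- tidy(report$robustness)
  rob$robust <- as.character(rob$robust)
  rob_out <- dplyr::bind_rows(
    rob,
    tibble(factor = "overall", side = NA_real_, deviation = NA_real_,
           s_statistic = NA_real_, criterion = NA_real_,
           robust = as.character(report$robustness$overall_robust))
  )
  readr::write_csv(rob_out, file.path(dir, "robustness.csv"))
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(dir, "report.txt"))
  invisible(dir)
}
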