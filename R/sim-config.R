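#' Simulation configuration for a CE assay
#'
#' Bundles every parameter the electropherogram simulator needs. The defaults
#' describe a validated ertapenem sodium assay: a six-level calibration series
#' (70--120 micrograms/mL, triplicate) whose corrected peak areas follow
#' `y = 2281.7 x - 24495`, an analyte migration time of 3.2 min, and a peak
#' width chosen so the theoretical plate number lands near 10,900.
#'
#' The response law is imposed on the *corrected* peak area (raw area divided
#' by migration time), the CE quantitation variable, so the configured line is
#' the simulator's ground truth for the downstream calibration fit.
#'
#' @param calibration_levels Numeric vector of calibration concentrations
#'   (micrograms/mL). All must be positive.
#' @param replicates Replicate runs per level.
#' @param response_slope Corrected-area units per microgram/mL.
#' @param response_intercept Corrected-area units.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   target corrected area of each run (corrected-area units).
#' @param migration_time Nominal analyte migration time (minutes).
#' @param migration_jitter_sd Run-to-run standard deviation of the apex time
#'   (minutes).
#' @param peak_sigma Gaussian peak width parameter sigma (minutes).
#' @param sampling_rate Detector sampling rate (points per minute).
#' @param run_length Total acquisition time (minutes).
#' @param baseline_drift_slope Linear baseline drift (mAU per minute).
#' @param baseline_noise_sd Point-wise detector noise on the signal (mAU).
#' @param seed Integer master seed; run-level sub-seeds are derived from it
#'   deterministically so a study is reproducible run by run.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(noise_sd = 0)
#' cfg$response_slope * 100 + cfg$response_intercept  # target area at 100
#' @export
sim_config <- function(calibration_levels = c(70, 80, 90, 100, 110, 120),
                       replicates = 3,
                       response_slope = 2281.7,
                       response_intercept = -24495,
                       noise_sd = 1000,
                       migration_time = 3.2,
                       migration_jitter_sd = 0.02,
                       peak_sigma = 0.031,
                       sampling_rate = 600,
                       run_length = 5,
                       baseline_drift_slope = 0.1,
                       baseline_noise_sd = 0.05,
                       seed = 1L) {
  if (!is.numeric(calibration_levels) || length(calibration_levels) < 1 ||
      any(!is.finite(calibration_levels)) || any(calibration_levels <= 0)) {
    abort("`calibration_levels` must be positive finite concentrations.")
  }
  check_number(replicates, "replicates", min = 1)
  check_number(response_slope, "response_slope")
  check_number(response_intercept, "response_intercept")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(migration_time, "migration_time", min = 0, strict_min = TRUE)
  check_number(migration_jitter_sd, "migration_jitter_sd", min = 0)
  check_number(peak_sigma, "peak_sigma", min = 0, strict_min = TRUE)
  check_number(sampling_rate, "sampling_rate", min = 0, strict_min = TRUE)
  check_number(run_length, "run_length", min = 0, strict_min = TRUE)
  check_number(baseline_drift_slope, "baseline_drift_slope")
  check_number(baseline_noise_sd, "baseline_noise_sd", min = 0)
  check_number(seed, "seed")

  cfg <- list(
    calibration_levels = as.numeric(calibration_levels),
    replicates = as.integer(replicates),
    response_slope = response_slope,
    response_intercept = response_intercept,
    noise_sd = noise_sd,
    migration_time = migration_time,
    migration_jitter_sd = migration_jitter_sd,
    peak_sigma = peak_sigma,
    sampling_rate = sampling_rate,
    run_length = run_length,
    baseline_drift_slope = baseline_drift_slope,
    baseline_noise_sd = baseline_noise_sd,
    seed = as.integer(seed)
  )

  # no negative target areas at the lowest calibration level
  min_area <- response_slope * min(cfg$calibration_levels) + response_intercept
  if (min_area <= 0) {
    abort(sprintf(
      "Response law gives a non-positive corrected area (%.4g) at the lowest calibration level %.4g.",
      min_area, min(cfg$calibration_levels)
    ))
  }
  # the sampling grid must cover migration_time +/- 6 peak sigma
  if (migration_time - 6 * peak_sigma < 0 ||
      migration_time + 6 * peak_sigma > run_length) {
    abort("`run_length` grid must cover `migration_time` +/- 6 * `peak_sigma`.")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  levels: %s ug/mL x %d replicates\n",
              paste(x$calibration_levels, collapse = ", "), x$replicates))
  cat(sprintf("  response: corrected area = %.6g * C %+.6g (noise sd %.4g)\n",
              x$response_slope, x$response_intercept, x$noise_sd))
  cat(sprintf("  peak: apex %.3g min (jitter sd %.3g), sigma %.3g min\n",
              x$migration_time, x$migration_jitter_sd, x$peak_sigma))
  cat(sprintf("  acquisition: %.3g min at %g pts/min; drift %.3g mAU/min, noise %.3g mAU\n",
              x$run_length, x$sampling_rate, x$baseline_drift_slope,
              x$baseline_noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
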