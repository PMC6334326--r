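#' Simulate a single electropherogram
#'
#' Renders one CE run as a uniformly sampled detector trace: a single Gaussian
#' analyte peak on a linear-drift baseline with i.i.d. Gaussian point noise.
#' The run's *corrected* peak area is drawn from the configured response law
#' (`slope * concentration + intercept` plus noise); the raw Gaussian area is
#' then that corrected area multiplied by the actual apex time, so that
#' downstream peak integration recovers the configured law exactly in the
#' noiseless case.
#'
#' @param config A [sim_config()].
#' @param concentration Analyte concentration in micrograms/mL.
#' @param seed Integer seed for this run (defaults to `config$seed`).
#' @param label Sample label stored in the metadata.
#'
#' @return A tibble of class `electropherogram` with columns `time_min` and
#'   `signal_mau`, and a `metadata` attribute recording the label, nominal
#'   concentration, ground-truth corrected area and apex time, the seed, and
#'   nominal run conditions.
#' @examples
#' eg <- simulate_electropherogram(sim_config(noise_sd = 0), 100)
#' attr(eg, "metadata")$true_corrected_area  # 2281.7 * 100 - 24495
#' @export
simulate_electropherogram <- function(config, concentration,
                                      seed = config$seed,
                                      label = "sample") {
  stopifnot(inherits(config, "sim_config"))
  check_number(concentration, "concentration", min = 0, strict_min = TRUE)
  withr::with_seed(as.integer(seed %% 2147483647), {
    target_corrected <- config$response_slope * concentration +
      config$response_intercept + rnorm(1, 0, config$noise_sd)
    if (target_corrected <= 0) {
      abort(sprintf(
        "Target corrected area is non-positive (%.4g) at concentration %.4g ug/mL.",
        target_corrected, concentration
      ))
    }
    apex <- config$migration_time + rnorm(1, 0, config$migration_jitter_sd)
    raw_area <- target_corrected * apex
    height <- raw_area / (config$peak_sigma * sqrt(2 * pi))

    time <- seq(0, config$run_length, by = 1 / config$sampling_rate)
    peak <- height * exp(-(time - apex)^2 / (2 * config$peak_sigma^2))
    signal <- peak + config$baseline_drift_slope * time +
      rnorm(length(time), 0, config$baseline_noise_sd)

    new_electropherogram(
      time, signal,
      metadata = list(
        sample_label = label,
        nominal_conc_ug_ml = concentration,
        true_corrected_area = target_corrected,
        true_apex_time_min = apex,
        seed = as.integer(seed %% 2147483647),
        conditions = list(
          voltage_kv = 15, buffer_mm = 10, buffer_ph = 7,
          temperature_c = 25, injection_s = 5, wavelength_nm = 214
        )
      )
    )
  })
}

new_electropherogram <- function(time, signal, metadata = list()) {
  if (length(time) != length(signal)) {
    abort("`time` and `signal` must have equal length.")
  }
  if (any(!is.finite(time)) || any(!is.finite(signal))) {
    abort("Electropherogram values must all be finite.")
  }
  if (any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  out <- tibble(time_min = as.numeric(time), signal_mau = as.numeric(signal))
  attr(out, "metadata") <- metadata
  class(out) <- c("electropherogram", class(out))
  out
}

#' Construct an electropherogram from time/signal vectors
#'
#' Wraps externally acquired (or hand-built) traces in the container the peak
#' processing functions expect.
#'
#' @param time_min Strictly increasing time grid (minutes).
#' @param signal_mau Detector signal (mAU), same length as `time_min`.
#' @param metadata Optional list of run metadata.
#' @return A tibble of class `electropherogram`.
#' @export
electropherogram <- function(time_min, signal_mau, metadata = list()) {
  new_electropherogram(time_min, signal_mau, metadata)
}

#' Simulate a full calibration study
#'
#' Generates `levels x replicates` runs, one electropherogram each, with
#' per-run sub-seeds derived deterministically from the master seed.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per run: `run_id`, `level`, `replicate`,
#'   `nominal_conc_ug_ml`, `seed`, and an `eg` list-column of
#'   electropherograms.
#' @examples
#' study <- simulate_calibration_study(sim_config())
#' nrow(study)  # 6 levels x 3 replicates = 18
#' @export
simulate_calibration_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr::expand_grid(
    level = seq_along(config$calibration_levels),
    replicate = seq_len(config$replicates)
  )
  grid |>
    dplyr::mutate(
      run_id = sprintf("cal_L%d_R%d", .data$level, .data$replicate),
      nominal_conc_ug_ml = config$calibration_levels[.data$level],
      seed = derive_seed(config$seed, dplyr::row_number()),
      eg = purrr::pmap(
        list(.data$nominal_conc_ug_ml, .data$seed, .data$run_id),
        function(conc, sd, id) {
          simulate_electropherogram(config, conc, seed = sd, label = id)
        }
      )
    ) |>
    dplyr::select("run_id", "level", "replicate", "nominal_conc_ug_ml",
                  "seed", "eg")
}

#' Simulate a system-suitability study
#'
#' `n` replicate runs at 100 micrograms/mL with independent response noise and
#' migration-time jitter, as used to check repeatability of corrected area,
#' migration time, plates and asymmetry before validation.
#'
#' @param config A [sim_config()].
#' @param n Number of replicate runs (>= 2, since an SD is required).
#' @param concentration Concentration of the replicate solutions
#'   (micrograms/mL).
#' @return A tibble with `run_id`, `nominal_conc_ug_ml`, `seed`, `eg`.
#' @export
simulate_sst_study <- function(config, n = 10, concentration = 100) {
  stopifnot(inherits(config, "sim_config"))
  check_number(n, "n", min = 2)
  tibble(
    run_id = sprintf("sst_%02d", seq_len(n)),
    nominal_conc_ug_ml = concentration,
    seed = derive_seed(config$seed, 10000 + seq_len(n))
  ) |>
    dplyr::mutate(eg = purrr::map2(.data$seed, .data$run_id, function(sd, id) {
      simulate_electropherogram(config, concentration, seed = sd, label = id)
    }))
}

#' Simulate a robustness study's assay contents
#'
#' Ground-truth generator for the Plackett-Burman screen: the content of run
#' *r* is `base_content + sum_j factor_effects[j] * level(r, j)` plus Gaussian
#' noise. With all effects zero this is a null (robust) method.
#'
#' @param design A Plackett-Burman design, e.g. [pb_design()].
#' @param factor_effects Numeric vector, one per design factor: content shift
#'   in % per unit level step (0 = that factor has no real effect).
#' @param base_content Content at nominal conditions (%, default 100).
#' @param noise_sd Assay noise on each run's content (%).
#' @param seed Integer seed.
#' @return A tibble `run_id`, `content_percent`.
#' @examples
#' simulate_robustness_study(pb_design(), rep(0, 7), noise_sd = 0)
#' @export
simulate_robustness_study <- function(design, factor_effects,
                                      base_content = 100,
                                      noise_sd = 0.3, seed = 1L) {
  mat <- validate_pb_design(design)
  if (length(factor_effects) != ncol(mat)) {
    abort(sprintf(
      "`factor_effects` must have one entry per design factor (%d), got %d.",
      ncol(mat), length(factor_effects)
    ))
  }
  check_number(base_content, "base_content")
  check_number(noise_sd, "noise_sd", min = 0)
  withr::with_seed(as.integer(seed %% 2147483647), {
    content <- base_content + drop(mat %*% factor_effects) +
      rnorm(nrow(mat), 0, noise_sd)
    tibble(run_id = seq_len(nrow(mat)), content_percent = content)
  })
}

#' Simulate a degraded sample
#'
#' Identical to [simulate_electropherogram()] except the analyte peak is
#' scaled by `1 - degraded_fraction`. No interfering degradation-product
#' peaks are synthesised: stress studies of this assay found none that
#' migrate with the analyte. Assaying such a run against an intact reference
#' therefore returns a content of `100 * (1 - degraded_fraction)` percent.
#'
#' @param config A [sim_config()].
#' @param degraded_fraction Fraction of analyte lost, in `[0, 1)`.
#' @param concentration Pre-degradation concentration (micrograms/mL).
#' @param seed Integer seed.
#' @return A tibble of class `electropherogram`; metadata records the
#'   degraded fraction.
#' @export
simulate_degraded_sample <- function(config, degraded_fraction,
                                     concentration = 100,
                                     seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(degraded_fraction) || length(degraded_fraction) != 1 ||
      !is.finite(degraded_fraction) ||
      degraded_fraction < 0 || degraded_fraction >= 1) {
    abort("`degraded_fraction` must lie in [0, 1).")
  }
  check_number(concentration, "concentration", min = 0, strict_min = TRUE)
  withr::with_seed(as.integer(seed %% 2147483647), {
    target_corrected <- config$response_slope * concentration +
      config$response_intercept + rnorm(1, 0, config$noise_sd)
    if (target_corrected <= 0) {
      abort(sprintf(
        "Target corrected area is non-positive (%.4g) at concentration %.4g ug/mL.",
        target_corrected, concentration
      ))
    }
    apex <- config$migration_time + rnorm(1, 0, config$migration_jitter_sd)
    scaled_corrected <- target_corrected * (1 - degraded_fraction)
    raw_area <- scaled_corrected * apex
    height <- raw_area / (config$peak_sigma * sqrt(2 * pi))
    time <- seq(0, config$run_length, by = 1 / config$sampling_rate)
    peak <- height * exp(-(time - apex)^2 / (2 * config$peak_sigma^2))
    signal <- peak + config$baseline_drift_slope * time +
      rnorm(length(time), 0, config$baseline_noise_sd)
    new_electropherogram(
      time, signal,
      metadata = list(
        sample_label = "degraded",
        nominal_conc_ug_ml = concentration,
        degraded_fraction = degraded_fraction,
        true_corrected_area = scaled_corrected,
        true_apex_time_min = apex,
        seed = as.integer(seed %% 2147483647)
      )
    )
  })
}

#' @export
autoplot.electropherogram <- function(object, ...) {
  meta <- attr(object, "metadata")
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$signal_mau)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Migration time (min)", y = "Signal (mAU)",
      title = if (!is.null(meta$sample_label)) meta$sample_label else NULL
    ) +
    ggplot2::theme_minimal()
}
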