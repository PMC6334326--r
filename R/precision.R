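#' Relative standard deviation summary
#'
#' Sample statistics with the `n - 1` SD denominator and
#' `RSD% = 100 * sd / mean`, the precision measure used throughout assay
#' validation.
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @return A one-row tibble: `n`, `mean`, `sd`, `rsd_percent`.
#' @examples
#' rsd(c(1, 2, 3))  # sd 1, mean 2, rsd 50%
#' @export
rsd <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be finite numbers.")
  }
  n <- length(values)
  if (n < 2) abort("RSD needs at least 2 values.")
  m <- mean(values)
  if (m == 0) abort("RSD is undefined for zero mean.")
  s <- sd(values)
  tibble(n = n, mean = m, sd = s, rsd_percent = 100 * s / m)
}

#' Assay content from corrected peak areas
#'
#' The external-standard content computation: the sample concentration is
#' `C_s = A_s * C_rs / A_rs` (sample area times reference-standard
#' concentration over reference-standard area) and the percentage content is
#' `C_s% = 100 * C_s / C_t` against the theoretical concentration.
#'
#' @param a_s Sample corrected peak area (>= 0).
#' @param a_rs Reference-standard corrected peak area (> 0).
#' @param c_rs Reference-standard concentration (micrograms/mL).
#' @param c_t Theoretical sample concentration (micrograms/mL, > 0).
#' @return A one-row tibble (vectorised over `a_s`): `cs`, `cs_percent`, and
#'   the echoed inputs.
#' @examples
#' assay_content(100, 100, 100, 100)  # 100%
#' @export
assay_content <- function(a_s, a_rs, c_rs, c_t) {
  if (any(!is.finite(c(a_s, a_rs, c_rs, c_t)))) {
    abort("All inputs must be finite.")
  }
  if (any(a_rs <= 0)) abort("`a_rs` must be > 0.")
  if (any(c_t <= 0)) abort("`c_t` must be > 0.")
  if (any(a_s < 0)) abort("`a_s` must be >= 0.")
  cs <- a_s * c_rs / a_rs
  tibble(
    cs = cs, cs_percent = 100 * cs / c_t,
    a_s = a_s, a_rs = a_rs, c_rs = c_rs, c_t = c_t
  )
}

#' Percentage recovery of a spiked standard
#'
#' The AOAC spike-recovery computation
#' `R% = 100 * (Cf - Cu) / Ca`: `Cf` is the total concentration measured
#' after spiking, `Cu` the unspiked formulation concentration, and `Ca` the
#' standard concentration added.
#'
#' @param cf,cu,ca Concentrations in micrograms/mL; `ca > 0`.
#' @return A tibble (vectorised): `r_percent`, `cf`, `cu`, `ca`.
#' @examples
#' recovery(80, 70, 10)  # 100%
#' @export
recovery <- function(cf, cu, ca) {
  if (any(!is.finite(c(cf, cu, ca)))) abort("All inputs must be finite.")
  if (any(ca <= 0)) abort("`ca` must be > 0.")
  tibble(r_percent = 100 * (cf - cu) / ca, cf = cf, cu = cu, ca = ca)
}

#' System-suitability summary
#'
#' Summarises replicate analyte peaks by the four SST metrics — corrected
#' area, migration time, plate number, asymmetry — reporting mean, SD and
#' RSD% per metric with a pass flag at the RSD acceptance limit.
#'
#' @param peaks A data frame with one row per replicate run and columns
#'   `corrected_area`, `apex_time`, `plate_number`, `asymmetry` (as from
#'   [process_study()]).
#' @param rsd_limit RSD acceptance limit in percent (default 2).
#' @return A four-row tibble: `metric`, `n`, `mean`, `sd`, `rsd_percent`,
#'   `pass`.
#' @export
sst_summary <- function(peaks, rsd_limit = 2) {
  stopifnot(is.data.frame(peaks))
  metrics <- c("corrected_area", "apex_time", "plate_number", "asymmetry")
  if (!all(metrics %in% names(peaks))) {
    abort(sprintf("`peaks` must contain columns: %s.",
                  paste(metrics, collapse = ", ")))
  }
  if (nrow(peaks) < 2) abort("SST summary needs at least 2 replicate peaks.")
  check_number(rsd_limit, "rsd_limit", min = 0, strict_min = TRUE)
  peaks |>
    dplyr::select(dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      rsd_percent = 100 * .data$sd / .data$mean,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      metric = factor(.data$metric, levels = metrics),
      pass = .data$rsd_percent <= rsd_limit
    ) |>
    dplyr::arrange(.data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
}

#' Intermediate (between-day) precision
#'
#' RSD of the day-level mean contents, the between-day component of
#' intermediate precision when each day contributes one (typically
#' triplicate-averaged) content value.
#'
#' @param day_results Numeric vector of per-day mean contents (%), length
#'   >= 2.
#' @return A one-row tibble as from [rsd()].
#' @examples
#' intermediate_precision(c(99, 101))  # rsd ~ 1.414%
#' @export
intermediate_precision <- function(day_results) {
  if (length(day_results) < 2) {
    abort("Intermediate precision needs results from at least 2 days.")
  }
  rsd(day_results)
}
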