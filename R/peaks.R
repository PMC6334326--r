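#' Estimate a linear baseline for an electropherogram
#'
#' Fits a straight line through the lowest-quartile signal points — points
#' that are, with overwhelming probability, off-peak — then refits on all
#' points not far above that line, so that subtracting the baseline leaves
#' noise with median near zero while the analyte peak is untouched.
#'
#' @param eg An `electropherogram` (or any data frame with `time_min` and
#'   `signal_mau` columns).
#' @return A list of class `baseline_model`: `baseline` (mAU at each time
#'   point), `intercept`, `slope`, `method`.
#' @export
estimate_baseline <- function(eg) {
  eg <- as_electropherogram_df(eg)
  if (nrow(eg) < 10) {
    abort("Electropherogram too short for baseline estimation (< 10 samples).")
  }
  thr <- quantile(eg$signal_mau, 0.25, names = FALSE)
  low <- eg$signal_mau <= thr
  if (sum(low) < 2) low <- rank(eg$signal_mau, ties.method = "first") <= 2
  fit <- lm(signal_mau ~ time_min, data = eg[low, ])
  b <- unname(coef(fit))
  # the quartile fit sits low by construction; refit on all points that are
  # not far above it (peaks excluded), which centres the baseline in the noise
  resid <- eg$signal_mau - (b[1] + b[2] * eg$time_min)
  scale <- stats::mad(resid[low], center = 0)
  if (is.finite(scale) && scale > 0) {
    keep <- resid < 5 * scale
    if (sum(keep) >= 2) {
      fit <- lm(signal_mau ~ time_min, data = eg[keep, ])
      b <- unname(coef(fit))
    }
  }
  structure(
    list(
      baseline = b[1] + b[2] * eg$time_min,
      intercept = b[1], slope = b[2],
      method = "lowest-quartile linear fit, off-peak refit"
    ),
    class = "baseline_model"
  )
}

as_electropherogram_df <- function(eg) {
  if (!is.data.frame(eg) || !all(c("time_min", "signal_mau") %in% names(eg))) {
    abort("Expected a data frame with `time_min` and `signal_mau` columns.")
  }
  eg
}

#' Detect peaks in an electropherogram
#'
#' Finds local maxima of the baseline-subtracted signal above `min_height`.
#' Each peak's integration window runs outward from the apex to the first
#' baseline crossing, starting no closer than the 0.1%-of-height points and
#' capped at apex +/- 6 sigma-equivalents (sigma estimated from the width at
#' half height); the cap keeps noiseless Gaussian tails essentially complete
#' without accumulating off-peak noise.
#'
#' @param eg An `electropherogram`.
#' @param baseline A [estimate_baseline()] result; computed if `NULL`.
#' @param min_height Minimum baseline-subtracted apex height (mAU). If
#'   `NULL`, uses `max(10 * mad(noise), 1)` where the noise scale comes from
#'   the baseline-subtracted lowest-quartile points.
#' @return A tibble with one row per detected peak: `peak`, `start_idx`,
#'   `apex_idx`, `end_idx`, `start_time`, `apex_time`, `end_time`, `height`,
#'   ordered by apex time. A blank run (no peak above threshold) returns an
#'   empty tibble with a warning.
#' @export
detect_peaks <- function(eg, baseline = NULL, min_height = NULL) {
  eg <- as_electropherogram_df(eg)
  if (is.null(baseline)) baseline <- estimate_baseline(eg)
  stopifnot(inherits(baseline, "baseline_model"))
  s <- eg$signal_mau - baseline$baseline
  n <- length(s)
  if (is.null(min_height)) {
    thr <- quantile(eg$signal_mau, 0.25, names = FALSE)
    noise <- s[eg$signal_mau <= thr]
    min_height <- max(10 * stats::mad(noise, center = 0), 1)
  }
  check_number(min_height, "min_height", min = 0, strict_min = TRUE)

  is_max <- c(FALSE, s[2:(n - 1)] >= s[1:(n - 2)] &
                s[2:(n - 1)] > s[3:n], FALSE)
  cand <- which(is_max & s > min_height)
  if (length(cand) == 0) {
    warn("No peak above `min_height`; treating run as blank.")
    return(tibble(
      peak = integer(), start_idx = integer(), apex_idx = integer(),
      end_idx = integer(), start_time = numeric(), apex_time = numeric(),
      end_time = numeric(), height = numeric()
    ))
  }

  # greedy acceptance of the tallest candidates; later candidates falling
  # inside an accepted window are noise ripple on the same peak
  cand <- cand[order(s[cand], decreasing = TRUE)]
  accepted <- list()
  for (i in cand) {
    inside <- any(vapply(accepted, function(w) {
      i >= w$start_idx && i <= w$end_idx
    }, logical(1)))
    if (inside) next
    accepted[[length(accepted) + 1]] <- peak_window(eg$time_min, s, i)
  }
  out <- dplyr::bind_rows(accepted) |> dplyr::arrange(.data$apex_idx)
  out |>
    dplyr::mutate(
      peak = dplyr::row_number(),
      start_time = eg$time_min[.data$start_idx],
      apex_time = eg$time_min[.data$apex_idx],
      end_time = eg$time_min[.data$end_idx],
      height = s[.data$apex_idx]
    ) |>
    dplyr::select("peak", "start_idx", "apex_idx", "end_idx",
                  "start_time", "apex_time", "end_time", "height")
}

# Integration window around apex index i of baseline-subtracted signal s:
# extend outward to the first baseline (zero) crossing, capped at apex
# +/- 6 sigma-equivalents so a crossing-free noiseless Gaussian is still
# integrated over an essentially complete (tail < 1e-8) finite window.
peak_window <- function(time, s, i) {
  h <- s[i]
  n <- length(s)

  # half-height crossings give the sigma estimate for the cap
  lh <- i; while (lh > 1 && s[lh] > h / 2) lh <- lh - 1
  rh <- i; while (rh < n && s[rh] > h / 2) rh <- rh + 1
  sigma_hat <- max((time[rh] - time[lh]) / 2.3548, .Machine$double.eps)
  t_lo <- time[i] - 6 * sigma_hat
  t_hi <- time[i] + 6 * sigma_hat

  l <- i
  while (l > 1 && s[l - 1] > 0 && time[l - 1] >= t_lo) l <- l - 1
  r <- i
  while (r < n && s[r + 1] > 0 && time[r + 1] <= t_hi) r <- r + 1
  tibble(start_idx = l, apex_idx = i, end_idx = r)
}

#' Measure peaks: the system-suitability metrology
#'
#' For each detected peak computes the quantities reported in CE system
#' suitability: apex (migration) time, baseline-subtracted height, raw area
#' (trapezoidal rule), corrected area (raw area / apex time), width at half
#' height, theoretical plate number `N = 5.54 (t / w_half)^2`, and the
#' asymmetry factor (trailing / leading half-width at 10% height; < 1 means
#' fronting). The apex time is refined by quadratic interpolation of the log
#' signal through the three points around the sampled maximum, which is exact
#' for a Gaussian peak.
#'
#' @param eg An `electropherogram`.
#' @param baseline A [estimate_baseline()] result; computed if `NULL`.
#' @param bounds A tibble of peak windows from [detect_peaks()]; computed if
#'   `NULL`.
#' @param ... Passed to [detect_peaks()] when `bounds` is `NULL`.
#' @return A tibble with one row per peak: `peak`, `apex_time`, `height`,
#'   `raw_area`, `corrected_area`, `width_half_height`, `plate_number`,
#'   `asymmetry`, `start_time`, `end_time`.
#' @examples
#' eg <- simulate_electropherogram(sim_config(noise_sd = 0), 100)
#' measure_peaks(eg)
#' @export
measure_peaks <- function(eg, baseline = NULL, bounds = NULL, ...) {
  eg <- as_electropherogram_df(eg)
  if (is.null(baseline)) baseline <- estimate_baseline(eg)
  if (is.null(bounds)) bounds <- detect_peaks(eg, baseline, ...)
  if (nrow(bounds) == 0) {
    return(tibble(
      peak = integer(), apex_time = numeric(), height = numeric(),
      raw_area = numeric(), corrected_area = numeric(),
      width_half_height = numeric(), plate_number = numeric(),
      asymmetry = numeric(), start_time = numeric(), end_time = numeric()
    ))
  }
  if (any(bounds$start_idx < 1) || any(bounds$end_idx > nrow(eg))) {
    abort("Peak bounds fall outside the signal range.")
  }
  s <- eg$signal_mau - baseline$baseline
  t <- eg$time_min
  purrr::pmap(
    list(bounds$peak, bounds$start_idx, bounds$apex_idx, bounds$end_idx),
    function(pk, l, i, r) measure_one_peak(pk, t, s, l, i, r)
  ) |>
    dplyr::bind_rows()
}

measure_one_peak <- function(pk, t, s, l, i, r) {
  seg_t <- t[l:r]
  seg_s <- s[l:r]

  # apex refinement: log-quadratic through the 3 points around the maximum
  # (exact for a Gaussian); falls back to plain quadratic if a neighbour is
  # non-positive
  ap <- refine_apex(t, s, i)
  apex_time <- ap$time
  height <- ap$height

  half <- height / 2
  above_half <- sum(seg_s >= half)
  if (above_half < 5) {
    abort(paste0(
      "Width at half height is not resolvable (fewer than 5 points across ",
      "the peak); increase `sampling_rate`."
    ))
  }
  w <- width_at(seg_t, seg_s, apex_time, half)
  width_half <- w$right - w$left

  # asymmetry factor at 10% height: trailing over leading half-width, so a
  # broad leading edge (fronting) gives values below 1
  w10 <- width_at(seg_t, seg_s, apex_time, 0.1 * height)
  asym <- (w10$right - apex_time) / (apex_time - w10$left)

  raw_area <- trapz(seg_t, seg_s)
  tibble(
    peak = pk,
    apex_time = apex_time,
    height = height,
    raw_area = raw_area,
    corrected_area = corrected_area(raw_area, apex_time),
    width_half_height = width_half,
    plate_number = 5.54 * (apex_time / width_half)^2,
    asymmetry = asym,
    start_time = seg_t[1],
    end_time = seg_t[length(seg_t)]
  )
}

refine_apex <- function(t, s, i) {
  n <- length(s)
  if (i <= 1 || i >= n) return(list(time = t[i], height = s[i]))
  y <- s[(i - 1):(i + 1)]
  x <- t[(i - 1):(i + 1)]
  if (all(y > 0)) y <- log(y)
  d <- (y[1] - 2 * y[2] + y[3])
  if (d >= 0) return(list(time = t[i], height = s[i]))
  # vertex of the parabola through three equally spaced points
  h <- x[2] - x[1]
  delta <- 0.5 * (y[1] - y[3]) / d * h
  tm <- x[2] + delta
  ym <- y[2] - 0.25 * (y[1] - y[3]) * delta / h
  list(time = tm, height = if (all(s[(i - 1):(i + 1)] > 0)) exp(ym) else ym)
}

# interpolated crossing times of level `lev` on each side of the apex
width_at <- function(seg_t, seg_s, apex_time, lev) {
  ia <- which.min(abs(seg_t - apex_time))
  left <- NA_real_
  for (j in seq(ia, 2)) {
    if (seg_s[j - 1] <= lev && seg_s[j] > lev) {
      left <- seg_t[j - 1] + (lev - seg_s[j - 1]) /
        (seg_s[j] - seg_s[j - 1]) * (seg_t[j] - seg_t[j - 1])
      break
    }
  }
  right <- NA_real_
  for (j in seq(ia, length(seg_s) - 1)) {
    if (seg_s[j + 1] <= lev && seg_s[j] > lev) {
      right <- seg_t[j] + (seg_s[j] - lev) /
        (seg_s[j] - seg_s[j + 1]) * (seg_t[j + 1] - seg_t[j])
      break
    }
  }
  if (!is.finite(left) || !is.finite(right)) {
    abort("Could not locate the requested height crossing within the peak window.")
  }
  list(left = left, right = right)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Velocity-corrected peak area
#'
#' In CE, analytes pass the fixed detection window at different velocities,
#' so raw areas are divided by migration time to make them comparable across
#' runs: `corrected = raw_area / apex_time`.
#'
#' @param raw_area Raw peak area (mAU * min), >= 0.
#' @param apex_time Migration time at the apex (min), > 0. Recycled against
#'   `raw_area`.
#' @return Corrected area(s).
#' @examples
#' corrected_area(100, 2)  # 50
#' @export
corrected_area <- function(raw_area, apex_time) {
  if (any(!is.finite(raw_area)) || any(!is.finite(apex_time))) {
    abort("`raw_area` and `apex_time` must be finite.")
  }
  if (any(apex_time <= 0)) abort("`apex_time` must be > 0.")
  raw_area / apex_time
}

#' Process one electropherogram to its main-peak metrology
#'
#' Convenience wrapper: baseline, detection, measurement, and selection of
#' the largest peak (by height) — the analyte peak in a single-analyte assay.
#'
#' @inheritParams detect_peaks
#' @return A one-row tibble as from [measure_peaks()], or a zero-row tibble
#'   for a blank.
#' @export
process_electropherogram <- function(eg, min_height = NULL) {
  bl <- estimate_baseline(eg)
  bounds <- detect_peaks(eg, bl, min_height = min_height)
  pk <- measure_peaks(eg, bl, bounds)
  if (nrow(pk) > 1) pk <- pk[which.max(pk$height), ]
  pk
}

#' Process every run of a simulated study
#'
#' Maps [process_electropherogram()] over a study tibble's `eg` list-column
#' and binds the per-run main-peak rows to the study metadata.
#'
#' @param study A tibble from [simulate_calibration_study()] or
#'   [simulate_sst_study()].
#' @param min_height Passed to peak detection.
#' @return The study tibble without `eg`, joined to the peak metrology
#'   columns.
#' @export
process_study <- function(study, min_height = NULL) {
  stopifnot(is.data.frame(study), "eg" %in% names(study))
  peaks <- purrr::map(study$eg, process_electropherogram,
                      min_height = min_height)
  keep <- vapply(peaks, nrow, integer(1)) == 1
  if (!all(keep)) {
    abort(sprintf("No analyte peak found in run(s): %s",
                  paste(study$run_id[!keep], collapse = ", ")))
  }
  dplyr::bind_cols(
    dplyr::select(study, -"eg"),
    dplyr::bind_rows(peaks) |> dplyr::select(-"peak")
  )
}
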