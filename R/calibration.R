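#' Fit a calibration line by ordinary least squares
#'
#' Regresses corrected peak area on nominal concentration over all replicate
#' points, the standard ICH linearity fit. The residual SD reported here is
#' taken about the fitted line (`n - 2` degrees of freedom) and is the
#' default `sigma` for [lod_loq()].
#'
#' @param data A data frame with one row per run.
#' @param conc,area Column names (tidy-eval) holding concentration
#'   (micrograms/mL) and corrected area. Defaults `concentration`,
#'   `corrected_area`.
#' @return An object of class `calibration_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `residual_sd`, `n`, the underlying `lm` model,
#'   and the data used. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(concentration = rep(c(1, 2, 3), each = 2))
#' d$corrected_area <- 2 * d$concentration
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, conc = "concentration",
                            area = "corrected_area") {
  d <- extract_xy(data, rlang::as_name(rlang::enquo(conc)),
                  rlang::as_name(rlang::enquo(area)))
  if (dplyr::n_distinct(d$x) < 2) {
    abort("Calibration needs at least 2 distinct concentration levels (slope undefined).")
  }
  model <- lm(y ~ x, data = d)
  # noiseless (exact-line) input is a legitimate use; keep lm's perfect-fit
  # caution out of the way
  sm <- withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  out <- list(
    slope = unname(coef(model)[2]),
    intercept = unname(coef(model)[1]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    n = nrow(d),
    model = model,
    data = d
  )
  structure(out, class = "calibration_fit")
}

extract_xy <- function(data, conc, area) {
  stopifnot(is.data.frame(data))
  if (!all(c(conc, area) %in% names(data))) {
    abort(sprintf("Columns `%s` and `%s` must be present.", conc, area))
  }
  tibble(x = as.numeric(data[[conc]]), y = as.numeric(data[[area]]))
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>\n")
  cat(sprintf("  y = %.6g x %+.6g   (n = %d)\n", x$slope, x$intercept, x$n))
  cat(sprintf("  R^2 = %.6f, residual SD = %.6g\n", x$r_squared, x$residual_sd))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p_value = unname(sm[, 4])
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    residual_sd = x$residual_sd,
    n = x$n
  )
}

#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Concentration (µg/mL)", y = "Corrected peak area",
                  subtitle = sprintf("y = %.5g x %+.5g,  R² = %.4f",
                                     object$slope, object$intercept,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Lack-of-fit ANOVA for calibration linearity
#'
#' Partitions the calibration variance into the classical five-row table used
#' to test linearity against pure (replicate) error:
#' between-concentration (df `k - 1`), linear regression (df 1), deviation
#' from linearity (df `k - 2`), residue / pure error (df `N - k`), and total
#' (df `N - 1`). `SS_between = r * sum((level mean - grand mean)^2)`,
#' `SS_regression = slope^2 * Sxx` over all points, `SS_deviation =
#' SS_between - SS_regression`, `SS_residue = SS_total - SS_between`. The
#' between, regression and deviation mean squares are each tested against
#' the residue mean square; the method is declared linear when the
#' deviation-of-linearity F stays below its critical value.
#'
#' @inheritParams fit_calibration
#' @param alpha Significance level for the critical F values (default 0.05).
#' @return A tibble of class `linearity_anova` with columns `source`, `df`,
#'   `ss`, `ms`, `f`, `f_crit`, `significant`.
#' @examples
#' d <- tidyr::expand_grid(concentration = c(1, 2, 3, 4), rep = 1:2)
#' d$corrected_area <- 2 * d$concentration + rnorm(nrow(d), 0, 0.1)
#' linearity_anova(d)
#' @export
linearity_anova <- function(data, alpha = 0.05, conc = "concentration",
                            area = "corrected_area") {
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1).")
  d <- extract_xy(data, rlang::as_name(rlang::enquo(conc)),
                  rlang::as_name(rlang::enquo(area)))
  k <- dplyr::n_distinct(d$x)
  if (k < 3) abort("Lack-of-fit ANOVA needs at least 3 concentration levels.")
  reps <- table(d$x)
  if (length(unique(as.integer(reps))) != 1 || any(reps < 2)) {
    abort(paste0(
      "Lack-of-fit ANOVA requires an equal replicate count (>= 2) per level; ",
      "use fit_calibration() alone for unbalanced data."
    ))
  }
  r <- as.integer(reps[1])
  n <- nrow(d)

  grand <- mean(d$y)
  level_means <- tapply(d$y, d$x, mean)
  ss_total <- sum((d$y - grand)^2)
  ss_between <- r * sum((level_means - grand)^2)
  sxx <- sum((d$x - mean(d$x))^2)
  slope <- sum((d$x - mean(d$x)) * (d$y - mean(d$y))) / sxx
  ss_regression <- slope^2 * sxx
  ss_residue <- ss_total - ss_between

  out <- assemble_anova(
    ss_between = ss_between, ss_regression = ss_regression,
    ss_residue = ss_residue, df_between = k - 1, df_residue = n - k,
    alpha = alpha
  )
  attr(out, "alpha") <- alpha
  out
}

#' Assemble a linearity ANOVA table from sums of squares
#'
#' Builds the five-row partition (between-concentration, linear regression,
#' deviation of linearity, residue, total) from pre-computed sums of squares
#' and degrees of freedom — as when reproducing a published ANOVA table whose
#' raw data are not available. Mean squares, F statistics against the residue
#' mean square, and critical F values at `alpha` are derived.
#'
#' @param ss_between,ss_regression,ss_residue Sums of squares (area^2 units).
#' @param df_between,df_residue Degrees of freedom; regression always has
#'   df 1 and deviation `df_between - 1`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `linearity_anova`.
#' @export
assemble_anova <- function(ss_between, ss_regression, ss_residue,
                           df_between, df_residue, alpha = 0.05) {
  for (v in c("ss_between", "ss_regression", "ss_residue")) {
    check_number(get(v), v, min = 0)
  }
  check_number(df_between, "df_between", min = 2)
  check_number(df_residue, "df_residue", min = 1)

  ss_deviation <- ss_between - ss_regression
  ss_total <- ss_between + ss_residue
  df <- c(df_between, 1, df_between - 1, df_residue,
          df_between + df_residue)
  ss <- c(ss_between, ss_regression, ss_deviation, ss_residue, ss_total)
  ms <- c(ss[1:4] / df[1:4], NA_real_)
  f <- c(ms[1:3] / ms[4], NA_real_, NA_real_)
  f_crit <- c(vapply(df[1:3], function(d1) f_critical(alpha, d1, df_residue),
                     numeric(1)), NA_real_, NA_real_)
  out <- tibble(
    source = c("between-concentration", "linear regression",
               "deviation of linearity", "residue", "total"),
    df = as.integer(df),
    ss = ss, ms = ms, f = f, f_crit = f_crit,
    significant = f > f_crit
  )
  class(out) <- c("linearity_anova", class(out))
  out
}

#' @export
tidy.linearity_anova <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "linearity_anova")
  out
}

#' Upper critical value of the F distribution
#'
#' @param alpha Significance level in (0, 1).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return The upper-`alpha` quantile of F(df1, df2).
#' @examples
#' round(f_critical(0.05, 5, 12), 2)  # 3.11
#' @export
f_critical <- function(alpha, df1, df2) {
  check_number(alpha, "alpha", min = 0, strict_min = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1).")
  check_number(df1, "df1", min = 1)
  check_number(df2, "df2", min = 1)
  qf(alpha, df1, df2, lower.tail = FALSE)
}

#' Limits of detection and quantitation
#'
#' The ICH calibration-based limits: `LOD = 3 sigma / S` and
#' `LOQ = 10 sigma / S`, where `S` is the calibration slope and `sigma` a
#' standard deviation of the response. Which SD plays the role of `sigma` is
#' a method choice: the residual SD of the calibration fit (default), the SD
#' of the intercept, or the SD of blank responses.
#'
#' @param sigma Response standard deviation (area units), >= 0.
#' @param slope Calibration slope (area units per microgram/mL), > 0.
#' @param sigma_source One of `"residual-sd"`, `"intercept-sd"`,
#'   `"blank-sd"` — recorded, not acted on.
#' @return A one-row tibble: `lod`, `loq` (micrograms/mL), `sigma`, `slope`,
#'   `sigma_source`. `loq / lod` is 10/3 by construction.
#' @examples
#' lod_loq(228.17, 2281.7)  # lod = 0.3
#' @export
lod_loq <- function(sigma, slope,
                    sigma_source = c("residual-sd", "intercept-sd",
                                     "blank-sd")) {
  sigma_source <- match.arg(sigma_source)
  check_number(sigma, "sigma", min = 0)
  check_number(slope, "slope", min = 0, strict_min = TRUE)
  tibble(
    lod = 3 * sigma / slope,
    loq = 10 * sigma / slope,
    sigma = sigma, slope = slope, sigma_source = sigma_source
  )
}

#' @rdname lod_loq
#' @param fit A [fit_calibration()] result; its residual SD and slope are
#'   used.
#' @export
lod_loq_from_fit <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  lod_loq(fit$residual_sd, fit$slope, "residual-sd")
}
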