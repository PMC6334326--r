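#' Canonical 15-run, 7-factor robustness design
#'
#' The three-level Plackett-Burman-style screening matrix used for CE method
#' robustness: `2n + 1 = 15` runs for `n = 7` factors, levels in
#' `{-1, 0, +1}` where 0 is the nominal operating condition. Each factor
#' column holds exactly four `+1`, four `-1` and seven `0` entries, and run 8
#' is the all-nominal run. This matrix embeds nominal levels in every run and
#' is stored as a literal fixture rather than generated from a standard
#' orthogonal PB construction.
#'
#' @return A tibble of class `pb_design`: `run` plus factor columns `A`--`G`.
#' @examples
#' d <- pb_design()
#' colSums(d[-1] == 1)  # four +1 per factor
#' @export
pb_design <- function() {
  m <- matrix(c(
    #  A   B   C   D   E   F   G
       1,  0,  0,  1,  0,  1,  1,   # run 1
       1,  1,  0,  0,  1,  0,  1,   # run 2
       1,  1,  1,  0,  0,  1,  0,   # run 3
       0,  1,  1,  1,  0,  0,  1,   # run 4
       1,  0,  1,  1,  1,  0,  0,   # run 5
       0,  1,  0,  1,  1,  1,  0,   # run 6
       0,  0,  1,  0,  1,  1,  1,   # run 7
       0,  0,  0,  0,  0,  0,  0,   # run 8 (all nominal)
      -1,  0,  0, -1,  0, -1, -1,   # run 9
      -1, -1,  0,  0, -1,  0, -1,   # run 10
      -1, -1, -1,  0,  0, -1,  0,   # run 11
       0, -1, -1, -1,  0,  0, -1,   # run 12
      -1,  0, -1, -1, -1,  0,  0,   # run 13
       0, -1,  0, -1, -1, -1,  0,   # run 14
       0,  0, -1,  0, -1, -1, -1    # run 15
  ), nrow = 15, byrow = TRUE,
  dimnames = list(NULL, LETTERS[1:7]))
  out <- dplyr::bind_cols(tibble(run = 1:15), as_tibble(m))
  class(out) <- c("pb_design", class(out))
  out
}

# Returns the bare 15 x 7 level matrix after checking the design invariants:
# entries in {-1, 0, 1} and the 4/4/7 column balance.
validate_pb_design <- function(design) {
  if (inherits(design, "pb_design") || is.data.frame(design)) {
    stopifnot(is.data.frame(design))
    cols <- setdiff(names(design), "run")
    mat <- as.matrix(design[cols])
  } else {
    mat <- as.matrix(design)
  }
  if (!all(mat %in% c(-1, 0, 1))) {
    abort("Design levels must all be -1, 0 or +1.")
  }
  bal_hi <- colSums(mat == 1)
  bal_lo <- colSums(mat == -1)
  bal_0 <- colSums(mat == 0)
  if (any(bal_hi != 4) || any(bal_lo != 4) || any(bal_0 != 7)) {
    abort("Each design factor must have exactly four +1, four -1 and seven 0 levels.")
  }
  mat
}

#' Default robustness factor definitions
#'
#' The seven operating parameters varied in the CE robustness screen, each
#' with its low / nominal / high physical setting (one unit of variation
#' about the nominal method).
#'
#' @return A tibble: `code`, `name`, `unit`, `low`, `nominal`, `high`.
#' @export
pb_factors <- function() {
  tibble(
    code = LETTERS[1:7],
    name = c("Buffer concentration", "Voltage", "Wavelength",
             "Injection time", "Rinsing of capillary",
             "Temperature of cartridge", "Temperature of sample storage"),
    unit = c("mM", "kV", "nm", "s", "min", "degC", "degC"),
    low = c(9, 14, 213, 4, 1, 24, 24),
    nominal = c(10, 15, 214, 5, 2, 25, 25),
    high = c(11, 16, 215, 6, 3, 26, 26)
  )
}

#' Map design levels to physical run settings
#'
#' Translates each `-1 / 0 / +1` entry of the design into the factor's
#' low / nominal / high physical value, giving the run sheet actually
#' executed at the instrument.
#'
#' @param design A [pb_design()] (or conforming data frame).
#' @param factors A factor table as from [pb_factors()]; must have one row
#'   per design column with `low < nominal < high`.
#' @return A tibble with `run` and one column per factor code holding
#'   physical values.
#' @examples
#' realize_design(pb_design(), pb_factors())
#' @export
realize_design <- function(design, factors = pb_factors()) {
  mat <- validate_pb_design(design)
  stopifnot(is.data.frame(factors),
            all(c("code", "low", "nominal", "high") %in% names(factors)))
  if (nrow(factors) != ncol(mat)) {
    abort(sprintf("Need %d factors to realise this design, got %d.",
                  ncol(mat), nrow(factors)))
  }
  if (any(factors$low >= factors$nominal | factors$nominal >= factors$high)) {
    abort("Each factor must satisfy low < nominal < high.")
  }
  phys <- purrr::map(seq_len(ncol(mat)), function(j) {
    lv <- mat[, j]
    ifelse(lv == 1, factors$high[j],
           ifelse(lv == -1, factors$low[j], factors$nominal[j]))
  })
  names(phys) <- factors$code
  dplyr::bind_cols(tibble(run = seq_len(nrow(mat))), as_tibble(phys))
}

#' Per-factor deviations from nominal conditions
#'
#' For each factor and each altered side (`+1`, `-1`), computes the absolute
#' deviation `D = |mean(content at the altered level) - mean(content at the
#' nominal level)|`, the Youden-Steiner effect measure. The nominal
#' reference for a factor is the mean over the seven runs where that factor
#' sits at level 0 (using all available data, consistent with the two-mean
#' presentation of the robustness results).
#'
#' @param design A [pb_design()] (or conforming data frame).
#' @param results A data frame with `run_id` and `content_percent`, one row
#'   per design run (any order; matched by `run_id` = run number).
#' @return A tibble of class `effect_table`: `factor`, `side`,
#'   `mean_altered`, `mean_nominal`, `deviation`.
#' @export
pb_effects <- function(design, results) {
  mat <- validate_pb_design(design)
  stopifnot(is.data.frame(results),
            all(c("run_id", "content_percent") %in% names(results)))
  if (nrow(results) != nrow(mat) ||
      !setequal(results$run_id, seq_len(nrow(mat)))) {
    abort(sprintf("`results` must contain exactly one content per run 1..%d.",
                  nrow(mat)))
  }
  content <- results$content_percent[order(results$run_id)]
  if (any(!is.finite(content))) abort("Run contents must all be finite.")

  out <- tidyr::expand_grid(
    factor = colnames(mat),
    side = c(1, -1)
  ) |>
    dplyr::mutate(
      mean_altered = purrr::map2_dbl(.data$factor, .data$side, function(f, s) {
        mean(content[mat[, f] == s])
      }),
      mean_nominal = purrr::map_dbl(.data$factor, function(f) {
        mean(content[mat[, f] == 0])
      }),
      deviation = abs(.data$mean_altered - .data$mean_nominal)
    )
  class(out) <- c("effect_table", class(out))
  out
}

#' Youden-Steiner robustness statistic
#'
#' Pools one side's seven factor deviations into
#' `S = sqrt((2/7) * sum(D^2))` and the acceptance criterion
#' `sqrt(2) * S`: a factor whose deviation stays below the criterion has no
#' significant effect at the scale of the overall experimental scatter.
#'
#' @param deviations Exactly 7 non-negative deviations (% content).
#' @return A one-row tibble: `s_statistic`, `criterion`.
#' @examples
#' youden_statistic(c(0.62, 1.03, 0.17, 1.01, 0.08, 0.40, 0.59))
#' @export
youden_statistic <- function(deviations) {
  if (!is.numeric(deviations) || length(deviations) != 7) {
    abort("`deviations` must hold exactly 7 values (one per factor).")
  }
  if (any(!is.finite(deviations)) || any(deviations < 0)) {
    abort("Deviations must be finite and >= 0.")
  }
  s <- sqrt(2 / 7 * sum(deviations^2))
  tibble(s_statistic = s, criterion = sqrt(2) * s)
}

#' Assess robustness from an effect table
#'
#' Applies the Youden-Steiner criterion per side: each factor's deviation
#' must be strictly below `sqrt(2) * S` of its side for the factor change to
#' be insignificant; the method is robust overall when all 14 factor-side
#' tests pass. The degenerate all-zero case (`D = criterion = 0`) is defined
#' to pass.
#'
#' @param effects An `effect_table` from [pb_effects()], or any data frame
#'   with `factor`, `side`, `deviation` covering 7 factors on both sides.
#' @return An object of class `youden_assessment`: `$table` (per factor-side
#'   deviations, criteria and robust flags), `$sides` (per-side S and
#'   criterion), `$overall_robust`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
assess_robustness <- function(effects) {
  stopifnot(is.data.frame(effects),
            all(c("factor", "side", "deviation") %in% names(effects)))
  if (!setequal(unique(effects$side), c(1, -1))) {
    abort("`effects` must contain both sides (+1 and -1).")
  }
  sides <- effects |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(
      youden_statistic(.data$deviation),
      .groups = "drop"
    )
  table <- effects |>
    dplyr::left_join(sides, by = "side") |>
    dplyr::mutate(
      robust = .data$deviation < .data$criterion |
        (.data$deviation == 0 & .data$criterion == 0)
    )
  structure(
    list(
      table = table,
      sides = sides,
      overall_robust = all(table$robust)
    ),
    class = "youden_assessment"
  )
}

#' @export
print.youden_assessment <- function(x, ...) {
  cat("<youden_assessment>\n")
  for (i in seq_len(nrow(x$sides))) {
    cat(sprintf("  side %+d: S = %.4f, criterion sqrt(2)*S = %.4f\n",
                x$sides$side[i], x$sides$s_statistic[i], x$sides$criterion[i]))
  }
  cat(sprintf("  factor-side tests passed: %d / %d\n",
              sum(x$table$robust), nrow(x$table)))
  cat(sprintf("  overall: %s\n",
              if (x$overall_robust) "ROBUST" else "NOT robust"))
  invisible(x)
}

#' @export
tidy.youden_assessment <- function(x, ...) {
  dplyr::select(x$table, "factor", "side", "deviation", "s_statistic",
                "criterion", "robust")
}

#' @export
glance.youden_assessment <- function(x, ...) {
  s <- x$sides
  tibble(
    s_plus = s$s_statistic[s$side == 1],
    criterion_plus = s$criterion[s$side == 1],
    s_minus = s$s_statistic[s$side == -1],
    criterion_minus = s$criterion[s$side == -1],
    overall_robust = x$overall_robust
  )
}

#' @export
autoplot.youden_assessment <- function(object, ...) {
  tab <- object$table |>
    dplyr::mutate(side_lab = sprintf("level %+d", .data$side))
  ggplot2::ggplot(tab, ggplot2::aes(.data$factor, .data$deviation)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$criterion),
                        linetype = 2, colour = "firebrick") +
    ggplot2::facet_wrap(~side_lab) +
    ggplot2::labs(x = "Factor", y = "Deviation D (% content)",
                  subtitle = "Dashed line: sqrt(2) * S acceptance criterion") +
    ggplot2::theme_minimal()
}
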