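#' Protonation-state fractions of a polyprotic analyte across pH
#'
#' Sequential macro-dissociation model: with `m` pKa values there are `m + 1`
#' protonation states, and the fraction of state `k` (0 = most protonated) at
#' a given pH is proportional to `10^(sum_{i<=k} (pH - pKa_i))`, normalised so
#' the fractions at each pH sum to one. This is the Henderson-Hasselbalch
#' speciation diagram used to pick an electrolyte pH at which a single species
#' dominates; for ertapenem's printed pKa values (3.22, 9.03) the singly
#' deprotonated species carries essentially all of the population at pH 7.
#'
#' @param pkas Strictly ascending numeric vector of macroscopic pKa values.
#' @param ph_grid Numeric vector of pH values to evaluate.
#' @return A tibble of class `species_profile` in long format with columns
#'   `ph`, `state` (integer, 0 = most protonated), and `fraction`; the `pkas`
#'   are kept as an attribute.
#' @examples
#' sp <- speciation_fractions(c(3.22, 9.03), seq(0, 14, by = 0.1))
#' dplyr::filter(sp, ph == 7)
#' @export
speciation_fractions <- function(pkas, ph_grid) {
  if (!is.numeric(pkas) || length(pkas) < 1 || any(!is.finite(pkas))) {
    abort("`pkas` must be a non-empty finite numeric vector.")
  }
  if (is.unsorted(pkas, strictly = TRUE)) {
    abort("`pkas` must be strictly ascending.")
  }
  if (!is.numeric(ph_grid) || any(!is.finite(ph_grid))) {
    abort("`ph_grid` values must be finite.")
  }
  m <- length(pkas)
  rows <- purrr::map(ph_grid, function(h) {
    # log10 relative population of each state; log-sum style normalisation
    lw <- cumsum(c(0, h - pkas))
    lw <- lw - max(lw)
    w <- 10^lw
    tibble(ph = h, state = 0:m, fraction = w / sum(w))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pkas") <- pkas
  class(out) <- c("species_profile", class(out))
  out
}

#' @export
autoplot.species_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$ph, .data$fraction,
                 colour = factor(.data$state),
                 group = factor(.data$state))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH", y = "Species fraction",
                  colour = "Deprotonation\nstate") +
    ggplot2::theme_minimal()
}
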