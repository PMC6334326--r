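# Shared fixtures and independent oracles used across the test files.

# noiseless simulation conditions: every stochastic term switched off
noiseless_config <- function(...) {
  sim_config(noise_sd = 0, migration_jitter_sd = 0, baseline_noise_sd = 0,
             ...)
}

# hand-built Gaussian trace on a flat or drifting baseline
gaussian_trace <- function(apex = 3.2, sigma = 0.02, height = 1,
                           from = 0, to = 5, rate = 600,
                           base_intercept = 0, base_slope = 0,
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(from, to, by = 1 / rate)
  s <- height * exp(-(t - apex)^2 / (2 * sigma^2)) +
    base_intercept + base_slope * t
  if (noise_sd > 0) s <- s + rnorm(length(t), 0, noise_sd)
  electropherogram(t, s)
}

# brute-force double-loop oracle for the ANOVA partition
brute_force_ss <- function(x, y) {
  grand <- sum(y) / length(y)
  ss_total <- 0
  for (i in seq_along(y)) ss_total <- ss_total + (y[i] - grand)^2
  levels <- sort(unique(x))
  ss_between <- 0
  for (lv in levels) {
    idx <- which(x == lv)
    m <- sum(y[idx]) / length(idx)
    ss_between <- ss_between + length(idx) * (m - grand)^2
  }
  list(ss_total = ss_total, ss_between = ss_between)
}

# brute-force group-by-mean oracle for the robustness effects
brute_force_effects <- function(design_mat, content) {
  out <- NULL
  for (f in colnames(design_mat)) {
    for (s in c(1, -1)) {
      m_alt <- mean(content[design_mat[, f] == s])
      m_nom <- mean(content[design_mat[, f] == 0])
      out <- rbind(out, data.frame(factor = f, side = s,
                                   deviation = abs(m_alt - m_nom)))
    }
  }
  out
}

extdata <- function(file) {
  system.file("extdata", file, package = "cevalidate", mustWork = TRUE)
}
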