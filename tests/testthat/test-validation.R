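test_that("calibration fit recovers exact lines and degenerate cases", {
  d <- tidyr::expand_grid(concentration = c(70, 80, 90, 100, 110, 120),
                          rep = 1:3) |>
    dplyr::mutate(corrected_area = 2281.7 * concentration - 24495)
  fit <- fit_calibration(d)
  expect_equal(fit$slope, 2281.7)
  expect_equal(fit$intercept, -24495)
  expect_equal(fit$r_squared, 1)
  # flat response -> zero slope
  flat <- tibble::tibble(concentration = c(1, 2, 3),
                         corrected_area = c(7, 7, 7))
  expect_equal(fit_calibration(flat)$slope, 0)
  # y = 2x through the origin
  prop <- tibble::tibble(concentration = 1:3, corrected_area = c(2, 4, 6))
  expect_equal(fit_calibration(prop)$slope, 2)
  expect_equal(fit_calibration(prop)$intercept, 0)
  # single level: slope undefined
  expect_error(fit_calibration(
    tibble::tibble(concentration = c(1, 1), corrected_area = c(1, 2))),
    "distinct")
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(5)
  d <- tidyr::expand_grid(concentration = c(1, 2, 3, 4), rep = 1:3) |>
    dplyr::mutate(corrected_area = 3 * concentration + rnorm(12, 0, 0.1))
  fit <- fit_calibration(d)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value"))
  expect_equal(td$estimate[td$term == "slope"], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$r_squared, fit$r_squared)
  expect_equal(gl$n, 12)
})

test_that("lack-of-fit ANOVA has the right structure on the study design", {
  set.seed(7)
  d <- tidyr::expand_grid(concentration = c(70, 80, 90, 100, 110, 120),
                          rep = 1:3) |>
    dplyr::mutate(corrected_area = 2281.7 * concentration - 24495 +
                    rnorm(18, 0, 1500))
  tab <- linearity_anova(d)
  expect_equal(tab$df, c(5L, 1L, 4L, 12L, 17L))
  expect_equal(tab$source[4], "residue")
  # noiseless data: no deviation, no residue
  d0 <- dplyr::mutate(d, corrected_area = 2281.7 * concentration - 24495)
  tab0 <- linearity_anova(d0)
  expect_equal(tab0$ss[tab0$source == "deviation of linearity"], 0,
               tolerance = 1e-8)
  expect_equal(tab0$ss[tab0$source == "residue"], 0, tolerance = 1e-8)
  # guards
  expect_error(linearity_anova(d[d$concentration < 90, ]), "3 concentration")
  unbalanced <- d[-1, ]
  expect_error(linearity_anova(unbalanced), "equal replicate")
})

test_that("ANOVA additivity and the brute-force oracle hold on random data", {
  for (case in 1:10) {
    set.seed(case)
    k <- sample(3:7, 1)
    r <- sample(2:5, 1)
    d <- tidyr::expand_grid(concentration = seq_len(k) * 10, rep = seq_len(r)) |>
      dplyr::mutate(corrected_area = rnorm(k * r, 50 * concentration, 25))
    tab <- linearity_anova(d)
    ss <- setNames(tab$ss, tab$source)
    df <- setNames(tab$df, tab$source)
    # df additivity
    expect_equal(df[["between-concentration"]] + df[["residue"]],
                 df[["total"]])
    expect_equal(df[["linear regression"]] + df[["deviation of linearity"]],
                 df[["between-concentration"]])
    # SS additivity to 1e-6 relative
    expect_equal(ss[["linear regression"]] + ss[["deviation of linearity"]],
                 ss[["between-concentration"]], tolerance = 1e-6)
    expect_equal(ss[["between-concentration"]] + ss[["residue"]],
                 ss[["total"]], tolerance = 1e-6)
    # MS = SS / df on testable rows
    expect_equal(tab$ms[1:4], tab$ss[1:4] / tab$df[1:4])
    # independent double-loop computation agrees
    oracle <- brute_force_ss(d$concentration, d$corrected_area)
    expect_equal(ss[["total"]], oracle$ss_total, tolerance = 1e-10)
    expect_equal(ss[["between-concentration"]], oracle$ss_between,
                 tolerance = 1e-10)
  }
})

test_that("regression F against line residuals equals the slope t squared", {
  for (case in 1:5) {
    set.seed(100 + case)
    d <- tidyr::expand_grid(concentration = c(2, 4, 6, 8), rep = 1:3) |>
      dplyr::mutate(corrected_area = rnorm(12, 5 * concentration + 1, 2))
    fit <- fit_calibration(d)
    sxx <- sum((d$concentration - mean(d$concentration))^2)
    rss <- sum(residuals(fit$model)^2)
    f_line <- fit$slope^2 * sxx / (rss / (fit$n - 2))
    t_slope <- tidy(fit)$statistic[2]
    expect_equal(f_line, t_slope^2, tolerance = 1e-6)
  }
})

test_that("critical F values match tabulated quantiles", {
  expect_equal(round(f_critical(0.05, 5, 12), 2), 3.11)
  expect_equal(round(f_critical(0.05, 1, 12), 2), 4.75)
  expect_equal(round(f_critical(0.05, 4, 12), 2), 3.26)
  expect_error(f_critical(0.05, 0, 12), ">= 1")
  expect_error(f_critical(1.5, 1, 12), "\\(0, 1\\)")
})

test_that("LOD/LOQ follow 3 and 10 sigma over slope", {
  expect_equal(lod_loq(0, 2281.7)$lod, 0)
  expect_equal(lod_loq(0, 2281.7)$loq, 0)
  ll <- lod_loq(228.17, 2281.7)
  expect_equal(ll$lod, 0.3)
  expect_equal(ll$loq, 1.0)
  # ratio identity for arbitrary sigma and slope
  for (case in 1:5) {
    set.seed(case)
    ll2 <- lod_loq(runif(1, 1, 500), runif(1, 10, 5000))
    expect_equal(ll2$loq / ll2$lod, 10 / 3)
  }
  expect_error(lod_loq(1, 0), "> 0")
})

test_that("RSD uses the sample SD and guards degenerate input", {
  expect_equal(rsd(c(5, 5, 5))$rsd_percent, 0)
  out <- rsd(c(1, 2, 3))
  expect_equal(out$sd, 1)
  expect_equal(out$mean, 2)
  expect_equal(out$rsd_percent, 50)
  # replicate migration times: SD rounds to 0.02 min
  sst <- readr::read_csv(extdata("ertapenem_sst_runs.csv"),
                         col_types = readr::cols())
  expect_equal(round(rsd(sst$apex_time)$sd, 2), 0.02)
  expect_error(rsd(7), "at least 2")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("content and recovery arithmetic match their definitions", {
  expect_equal(assay_content(123, 123, 100, 100)$cs_percent, 100)
  expect_equal(assay_content(0, 123, 100, 100)$cs_percent, 0)
  expect_equal(assay_content(0.9994 * 123, 123, 100, 100)$cs_percent, 99.94)
  expect_error(assay_content(1, 0, 100, 100), "> 0")
  expect_error(assay_content(1, 1, 100, 0), "> 0")
  expect_equal(recovery(80, 70, 10)$r_percent, 100)
  expect_equal(recovery(70, 70, 10)$r_percent, 0)
  expect_equal(recovery(100, 70, 30)$r_percent, 100)
  expect_error(recovery(80, 70, 0), "> 0")
})

test_that("SST summary covers the four metrics with pass flags", {
  # identical replicate peaks: all RSD zero, all pass
  ident <- tibble::tibble(corrected_area = rep(2e5, 10),
                          apex_time = rep(3.2, 10),
                          plate_number = rep(11000, 10),
                          asymmetry = rep(0.84, 10))
  tab <- sst_summary(ident)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$rsd_percent == 0))
  expect_true(all(tab$pass))
  # one metric over the limit fails
  wide <- dplyr::mutate(ident, plate_number = c(rep(11000, 9), 12500))
  tab2 <- sst_summary(wide, rsd_limit = 2)
  expect_false(tab2$pass[tab2$metric == "plate_number"])
  expect_true(tab2$pass[tab2$metric == "apex_time"])
  # simulated SST study: 4 finite rows
  sst <- simulate_sst_study(sim_config(seed = 3), n = 10)
  tab3 <- sst_summary(process_study(sst))
  expect_equal(nrow(tab3), 4)
  expect_true(all(is.finite(tab3$rsd_percent)))
  expect_error(sst_summary(ident[1, ]), "at least 2")
})

test_that("intermediate precision is the RSD of day means", {
  expect_equal(intermediate_precision(c(100, 100, 100))$rsd_percent, 0)
  two <- intermediate_precision(c(99, 101))
  expect_equal(two$mean, 100)
  expect_equal(two$sd, sqrt(2))
  expect_equal(two$rsd_percent, 100 * sqrt(2) / 100)
  three <- intermediate_precision(c(102.84, 99.83, 99.15))
  expect_equal(three$rsd_percent, 1.9519, tolerance = 1e-4)
  expect_error(intermediate_precision(100), "2 days")
})

test_that("mean fitted slope on noisy studies stays near the true slope", {
  # 50 simulated calibration studies, response noise SD 1000
  slopes <- vapply(1:50, function(i) {
    cfg <- sim_config(noise_sd = 1000, seed = 1000 + i)
    study <- simulate_calibration_study(cfg)
    truth <- tibble::tibble(
      concentration = study$nominal_conc_ug_ml,
      corrected_area = purrr::map_dbl(study$eg,
                                      ~ attr(.x, "metadata")$true_corrected_area)
    )
    fit_calibration(truth)$slope
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 2281.7), 3 * se)
})
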