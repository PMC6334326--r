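test_that("the canonical design satisfies its balance invariants", {
  d <- pb_design()
  mat <- as.matrix(d[LETTERS[1:7]])
  expect_equal(nrow(mat), 15)  # 2n + 1 runs for n = 7 factors
  expect_equal(ncol(mat), 7)
  expect_equal(unname(colSums(mat == 1)), rep(4L, 7))
  expect_equal(unname(colSums(mat == -1)), rep(4L, 7))
  expect_equal(unname(colSums(mat == 0)), rep(7L, 7))
  expect_equal(unname(mat[8, ]), rep(0, 7))   # all-nominal run
  expect_equal(unname(mat[1, "A"]), 1)        # first run has factor A high
})

test_that("malformed designs are rejected", {
  d <- pb_design()
  bad <- d
  bad$A[1] <- 2
  expect_error(pb_effects(bad, tibble::tibble(run_id = 1:15,
                                              content_percent = rep(100, 15))),
               "-1, 0 or \\+1")
  unbalanced <- d
  unbalanced$A[1] <- 0
  expect_error(cevalidate:::validate_pb_design(unbalanced), "four \\+1")
})

test_that("design levels realise to physical settings", {
  phys <- realize_design(pb_design(), pb_factors())
  expect_equal(phys$A[1], 11)    # buffer at +1 -> 11 mM
  expect_equal(phys$B[9], 15)    # voltage at 0 -> 15 kV
  expect_equal(unname(unlist(phys[8, LETTERS[1:7]])),
               pb_factors()$nominal)  # nominal run
  expect_error(realize_design(pb_design(), pb_factors()[1:5, ]), "7 factors")
  bad <- pb_factors()
  bad$low[1] <- bad$high[1]
  expect_error(realize_design(pb_design(), bad), "low < nominal < high")
})

test_that("effects are two-group mean deviations and match a brute-force oracle", {
  design <- pb_design()
  # constant contents: all deviations zero
  const <- tibble::tibble(run_id = 1:15, content_percent = rep(100, 15))
  eff0 <- pb_effects(design, const)
  expect_equal(eff0$deviation, rep(0, 14))
  # random contents: agreement with the independent group-by-mean oracle
  mat <- as.matrix(design[LETTERS[1:7]])
  for (case in 1:10) {
    set.seed(case)
    res <- tibble::tibble(run_id = 1:15,
                          content_percent = rnorm(15, 100, 1))
    eff <- pb_effects(design, res)
    oracle <- brute_force_effects(mat, res$content_percent)
    joined <- merge(eff, oracle, by = c("factor", "side"))
    expect_equal(joined$deviation.x, joined$deviation.y, tolerance = 1e-12)
  }
  expect_error(pb_effects(design, const[-1, ]), "one content per run")
})

test_that("effects recover imposed group means", {
  design <- pb_design()
  mat <- as.matrix(design[LETTERS[1:7]])
  # factor A: altered (+1) runs at 100.84, nominal runs at 100.22
  content <- rep(100, 15)
  content[mat[, "A"] == 1] <- 100.84
  content[mat[, "A"] == 0] <- 100.22
  eff <- pb_effects(design, tibble::tibble(run_id = 1:15,
                                           content_percent = content))
  expect_equal(eff$deviation[eff$factor == "A" & eff$side == 1], 0.62)
  # factor E: altered (-1) runs at 100.68, nominal at 100.02
  content2 <- rep(100, 15)
  content2[mat[, "E"] == -1] <- 100.68
  content2[mat[, "E"] == 0] <- 100.02
  eff2 <- pb_effects(design, tibble::tibble(run_id = 1:15,
                                            content_percent = content2))
  expect_equal(eff2$deviation[eff2$factor == "E" & eff2$side == -1], 0.66)
})

test_that("the Youden statistic and criterion follow their closed forms", {
  # all deviations equal d: S = d sqrt(2), criterion = 2d, every D passes
  for (d in c(0.1, 1, 7)) {
    ys <- youden_statistic(rep(d, 7))
    expect_equal(ys$s_statistic, d * sqrt(2))
    expect_equal(ys$criterion, 2 * d)
  }
  # criterion / S is exactly sqrt(2) for arbitrary input
  for (case in 1:5) {
    set.seed(case)
    ys <- youden_statistic(runif(7, 0, 3))
    expect_equal(ys$criterion / ys$s_statistic, sqrt(2))
  }
  expect_error(youden_statistic(rep(1, 6)), "exactly 7")
  expect_error(youden_statistic(c(rep(1, 6), -1)), ">= 0")
})

test_that("scaling all deviations rescales S but not the verdict", {
  set.seed(9)
  base <- runif(7, 0, 2)
  effects <- dplyr::bind_rows(
    tibble::tibble(factor = LETTERS[1:7], side = 1, deviation = base),
    tibble::tibble(factor = LETTERS[1:7], side = -1, deviation = rev(base))
  )
  a1 <- assess_robustness(effects)
  for (k in c(0.2, 5)) {
    scaled <- dplyr::mutate(effects, deviation = deviation * k)
    a2 <- assess_robustness(scaled)
    expect_equal(a2$sides$s_statistic, k * a1$sides$s_statistic)
    expect_equal(a2$sides$criterion, k * a1$sides$criterion)
    expect_equal(a2$table$robust, a1$table$robust)
  }
})

test_that("a single dominant deviation is flagged, zeros pass vacuously", {
  effects <- tidyr::expand_grid(factor = LETTERS[1:7], side = c(1, -1)) |>
    dplyr::mutate(deviation = ifelse(factor == "A" & side == 1, 10, 0.01))
  a <- assess_robustness(effects)
  tab <- a$table
  expect_false(tab$robust[tab$factor == "A" & tab$side == 1])
  expect_false(a$overall_robust)
  # all-zero degenerate case is defined to pass
  zero <- tidyr::expand_grid(factor = LETTERS[1:7], side = c(1, -1)) |>
    dplyr::mutate(deviation = 0)
  az <- assess_robustness(zero)
  expect_true(az$overall_robust)
  expect_equal(az$sides$criterion, c(0, 0))
})

test_that("null robustness studies rarely flag factors (Monte Carlo)", {
  design <- pb_design()
  flags <- vapply(1:200, function(i) {
    runs <- simulate_robustness_study(design, rep(0, 7), noise_sd = 0.3,
                                      seed = 5000 + i)
    a <- assess_robustness(pb_effects(design, runs))
    mean(!a$table$robust)
  }, numeric(1))
  expect_lt(mean(flags), 0.20)
})

test_that("tidy/glance on an assessment expose the verdict", {
  runs <- simulate_robustness_study(pb_design(), rep(0, 7), noise_sd = 0.3,
                                    seed = 1)
  a <- assess_robustness(pb_effects(pb_design(), runs))
  td <- tidy(a)
  expect_equal(nrow(td), 14)
  gl <- glance(a)
  expect_identical(gl$overall_robust, a$overall_robust)
  expect_equal(gl$criterion_plus / gl$s_plus, sqrt(2))
})
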