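test_that("a noise-free probit line is recovered exactly", {
  doses <- dose_ladder(0.05, k = 6)
  d <- exact_bioassay(0.05, 1.53, doses)
  fit <- fit_probit(d)
  expect_equal(fit$slope, 1.53, tolerance = 1e-6)
  expect_equal(-fit$intercept / fit$slope, log10(0.05), tolerance = 1e-6)
  expect_equal(fit$lc50, 0.05, tolerance = 1e-6)
  expect_lt(fit$gof_chi2, 1e-8)
  expect_equal(fit$gof_df, 4L)
  expect_false(fit$censored)
})

test_that("LC50 and its Fieller interval behave as a ratio estimate", {
  set.seed(11)
  cfg <- sim_config()
  d <- simulate_bioassay(cfg, strain = "Sus", doses = dose_ladder(0.05),
                         include_control = FALSE, seed = 31L)
  fit <- fit_probit(d)
  expect_true(fit$lc50_ci95[1L] < fit$lc50 && fit$lc50 < fit$lc50_ci95[2L])
  # invariant under reordering of dose groups
  fit2 <- fit_probit(d[sample(nrow(d)), ])
  expect_equal(fit2$lc50, fit$lc50)
  expect_equal(fit2$gof_chi2, fit$gof_chi2)
  # heterogeneity inflation can only widen the interval
  plain <- fit_probit(d, heterogeneity_ci = FALSE)
  if (fit$gof_chi2 > fit$gof_df) {
    expect_gte(diff(fit$lc50_ci95), diff(plain$lc50_ci95))
  } else {
    expect_equal(fit$lc50_ci95, plain$lc50_ci95)
  }
})

test_that("an LC50 above the tested range is reported as a censored bound", {
  # resistant-strain-like: barely any response up to the top concentration
  d <- data.frame(strain = "BA-R", compound = "flubendiamide",
                  concentration_ug_cm2 = c(2.27, 22.7, 227),
                  n_treated = 262, n_dead = c(2, 6, 16))
  fit <- fit_probit(d)
  expect_true(fit$censored)
  expect_equal(fit$lc50, 227)
  expect_true(all(is.na(fit$lc50_ci95)))
  expect_match(utils::capture.output(print(fit))[2L], ">227")
})

test_that("degenerate designs are rejected", {
  d <- exact_bioassay(0.05, 1.5, c(0.01, 0.1))
  expect_error(fit_probit(d), "3 distinct")
  d <- data.frame(strain = "S", compound = "c",
                  concentration_ug_cm2 = c(1, 2, 4),
                  n_treated = 64, n_dead = 64)
  expect_error(fit_probit(d), "identifiable")
  two <- data.frame(strain = rep(c("a", "b"), each = 3), compound = "c",
                    concentration_ug_cm2 = rep(c(1, 2, 4), 2),
                    n_treated = 64, n_dead = 1)
  expect_error(fit_probit(two), "single strain")
})

test_that("resistance ratios divide LC50s and track censoring", {
  expect_equal(resistance_ratio(40.4, 0.010)$value, 4040)
  expect_equal(resistance_ratio(3.09, 0.002)$value, 1545)
  expect_equal(resistance_ratio(1.7, 1.7)$value, 1)
  a <- fit_probit(exact_bioassay(0.05, 1.5, dose_ladder(0.05)))
  b <- fit_probit(exact_bioassay(7.1, 1.7, dose_ladder(7.1)))
  expect_equal(resistance_ratio(a, b)$value * resistance_ratio(b, a)$value, 1,
               tolerance = 1e-12)
  cen <- fit_probit(data.frame(strain = "R", compound = "c",
                               concentration_ug_cm2 = c(2.27, 22.7, 227),
                               n_treated = 262, n_dead = c(2, 6, 16)))
  expect_true(resistance_ratio(cen, a)$is_lower_bound)
  expect_error(resistance_ratio(a, cen), "censored")
})

test_that("equality and parallelism tests are nested likelihood-ratio tests", {
  cfg <- sim_config()
  d <- simulate_bioassay(cfg, strain = "Sus", doses = dose_ladder(0.05),
                         include_control = FALSE, seed = 5L)
  self <- compare_probit_lines(d, transform(d, strain = "Sus2"))
  expect_equal(self$equality_chi2, 0, tolerance = 1e-8)
  expect_equal(self$parallelism_chi2, 0, tolerance = 1e-8)

  set.seed(21)
  null_p <- numeric(100); eq_ge_par <- logical(100)
  for (i in seq_len(100)) {
    a <- simulate_bioassay(cfg, strain = "a", doses = dose_ladder(0.05),
                           include_control = FALSE, seed = NULL)
    b <- simulate_bioassay(cfg, strain = "b", doses = dose_ladder(0.05),
                           include_control = FALSE, seed = NULL)
    cmp <- compare_probit_lines(a, b)
    null_p[i] <- cmp$equality_p
    eq_ge_par[i] <- cmp$equality_chi2 >= cmp$parallelism_chi2 - 1e-8
  }
  # same generating line: nominal behaviour under the null
  expect_gte(mean(null_p > 0.05), 0.88)
  # nested models: the 2-df statistic dominates the 1-df statistic
  expect_true(all(eq_ge_par))
})

test_that("widely separated lines are detected with p < 0.001", {
  cfg <- sim_config()
  set.seed(22)
  p <- replicate(60, {
    sus <- simulate_bioassay(cfg, strain = "Sus", doses = dose_ladder(0.05),
                             include_control = FALSE, seed = NULL)
    res <- simulate_bioassay(cfg, mix = c(SS = 0, RS = 0, RR = 1),
                             strain = "TF-R", doses = dose_ladder(50),
                             include_control = FALSE, seed = NULL)
    compare_probit_lines(sus, res)$equality_p
  })
  expect_true(all(p < 0.001))
})

test_that("probit recovery is unbiased at the reference design size", {
  cfg <- sim_config()
  set.seed(33)
  lc <- numeric(60); sl <- numeric(60)
  for (i in seq_len(60)) {
    d <- simulate_bioassay(cfg, strain = "Sus", doses = dose_ladder(0.05),
                           n_per_dose = 64, include_control = FALSE,
                           seed = NULL)
    f <- fit_probit(d)
    lc[i] <- f$lc50; sl[i] <- f$slope
  }
  expect_equal(mean(lc), 0.05, tolerance = 0.05)
  expect_equal(mean(sl), 1.53, tolerance = 0.05)
})

test_that("probit_table mirrors the summary-table layout", {
  a <- fit_probit(exact_bioassay(0.05, 1.53, dose_ladder(0.05),
                                 strain = "Sus"))
  b <- fit_probit(exact_bioassay(7.13, 1.73, dose_ladder(7.13),
                                 strain = "BA-R"))
  tab <- probit_table(list(a, b), reference = "Sus")
  expect_equal(tab$rr[tab$strain == "BA-R"], 7.13 / 0.05, tolerance = 1e-4)
  expect_true(is.na(tab$rr[tab$strain == "Sus"]) ||
                tab$rr[tab$strain == "Sus"] == 1)
  expect_setequal(
    c("strain", "compound", "n", "lc50", "ci_low", "ci_high", "slope",
      "slope_se", "chi2", "df", "rr", "censored"),
    names(tab))
})
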