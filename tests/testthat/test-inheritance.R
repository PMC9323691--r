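test_that("Stone's D places the F1 between the parental log-LC50s", {
  d <- stone_dominance(0.05, 227, 0.07, res_censored = TRUE)
  expect_equal(round(d$value, 2), -0.92)
  expect_true(d$is_bound)
  expect_match(utils::capture.output(print(d)), "<", fixed = TRUE)

  expect_equal(stone_dominance(0.03, 12, 12)$value, 1)
  expect_equal(stone_dominance(0.03, 12, sqrt(0.03 * 12))$value, 0,
               tolerance = 1e-12)
  # unit invariance: a common rescaling of all LC50s cancels
  for (k in c(0.1, 7, 1000)) {
    expect_equal(stone_dominance(0.05 * k, 227 * k, 0.07 * k)$value,
                 stone_dominance(0.05, 227, 0.07)$value, tolerance = 1e-10)
  }
  expect_error(stone_dominance(1, 1, 1), "equal")
})

test_that("Bourguet effective dominance matches the reciprocal-cross table", {
  expect_equal(round(bourguet_dominance(87.50, 71.35, 0.00)$value, 2), 0.18)
  expect_equal(round(bourguet_dominance(64.58, 59.38, 0.00)$value, 2), 0.08)
  # heterozygote indistinguishable from the susceptible parent
  expect_equal(bourguet_dominance(40, 40, 0)$value, 0)
  # control row: natural mortality in Sus only gives complete dominance
  expect_equal(bourguet_dominance(2.08, 0, 0)$value, 1)
  # undefined dose renders as a missing value, not an error
  und <- bourguet_dominance(50, 30, 50)
  expect_true(is.na(und$value))
  # clipping keeps the raw value alongside
  clipped <- bourguet_dominance(14.58, 21.87, 0)
  expect_equal(clipped$value, 0)
  expect_equal(clipped$raw, -0.5, tolerance = 1e-3)
  expect_equal(bourguet_dominance(14.58, 21.87, 0, clip = FALSE)$value,
               clipped$raw)
})

test_that("dominance labels partition the D scale", {
  expect_equal(dominance_label(-0.92), "(incompletely) recessive")
  expect_equal(dominance_label(0.1), "additive")
  expect_equal(dominance_label(0.7), "dominant")
})

test_that("Mendelian backcross expectation averages F1 and resistant mortality", {
  expect_equal(backcross_expected_mortality(4.69, 0.00), 2.345)
  expect_equal(backcross_expected_mortality(100, 100), 100)
  for (m in c(0, 17.2, 63)) {
    expect_equal(backcross_expected_mortality(m, m), m)
  }
  expect_error(backcross_expected_mortality(120, 0))
})

test_that("the monogenic chi-square reproduces the printed backcross column", {
  expect_equal(monogenic_chi_square(0.3125, 0.3906, 64)$chi2, 1.64,
               tolerance = 0.005)
  expect_equal(monogenic_chi_square(0.5938, 0.505, 64)$chi2, 2.02,
               tolerance = 0.005)
  expect_equal(monogenic_chi_square(0.4, 0.4, 64)$chi2, 0)
  expect_error(monogenic_chi_square(0.5, 1, 64), "degenerate")

  # every printed row of the reference backcross recomputes within 0.1
  tab <- table2_barf_backcross
  rec <- monogenic_chi_square(tab$obs_pct / 100, tab$exp_pct / 100, 64)
  expect_true(all(abs(rec$chi2 - tab$chi2) < 0.1))
  # significance flags: only the lowest concentration differs
  expect_equal(rec$significant, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("the monogenic statistic is the 2-cell Pearson chi-square", {
  set.seed(9)
  p_obs <- runif(500); p_exp <- runif(500, 0.01, 0.99)
  n <- sample(16:512, 500, replace = TRUE)
  ours <- monogenic_chi_square(p_obs, p_exp, n)$chi2
  dead <- n * p_obs
  pearson <- (dead - n * p_exp)^2 / (n * p_exp) +
    ((n - dead) - n * (1 - p_exp))^2 / (n * (1 - p_exp))
  expect_equal(ours, pearson, tolerance = 1e-12)
  # dead/alive complement symmetry
  flipped <- monogenic_chi_square(1 - p_obs, 1 - p_exp, n)$chi2
  expect_equal(ours, flipped, tolerance = 1e-12)
})

test_that("monogenic_table mixes observed and predicted expectations", {
  cfg <- sim_config()
  cr <- simulate_crosses(cfg, seed = 17L)
  f1 <- fit_probit(cr$f1_h1); res <- fit_probit(cr$res)
  mixed <- monogenic_table(cr$bc1, f1, res,
                           f1_records = cr$f1_h1, res_records = cr$res)
  expect_equal(nrow(mixed), length(cfg$dose_grid))
  # at a dose absent from the parental tables the probit prediction is used
  extra <- cr$bc1
  extra$concentration_ug_cm2[extra$concentration_ug_cm2 == 0.41] <- 0.5
  m2 <- monogenic_table(extra, f1, res,
                        f1_records = cr$f1_h1, res_records = cr$res)
  pred <- 100 * (predict_mortality(f1, 0.5) + predict_mortality(res, 0.5)) / 2
  expect_equal(m2$expected_pct[m2$concentration == 0.5], pred)
  expect_error(monogenic_table(extra, f1, res,
                               f1_records = cr$f1_h1, res_records = cr$res,
                               rule = "observed"), "0.5")
})

test_that("Lande's effective-factor count obeys its closed-form limits", {
  # monogenic limit: range^2 = 8 sigma2_s
  ef <- lande_effective_factors(2, 0, 0.5 + 0.1, 0.1)
  expect_equal(ef$n_e, 1)
  # doubling the segregational variance halves n_e
  half <- lande_effective_factors(2, 0, 1.0 + 0.1, 0.1)
  expect_equal(half$n_e, ef$n_e / 2)
  expect_error(lande_effective_factors(2, 0, 0.1, 0.2), "segregating")
  expect_equal(tolerance_variance(2), 0.25)
})

test_that("Lande recovery on simulated recessive crosses matches the closed form", {
  # closed-form oracle for the generating one-locus recessive model:
  # between-class BC variance (d/2)^2 with d = log10(227/0.07), plus the
  # mean within-class variance (1/1.53^2 + 1/0.70^2)/2, minus the F1
  # variance 1/1.53^2, gives sigma2_s ~ 3.89 and
  # n_e = log10(227/0.05)^2 / (8 * 3.89) ~ 0.43
  cfg <- sim_config()
  set.seed(44)
  ne <- replicate(60, {
    cr <- simulate_crosses(cfg, seed = NULL)
    fs <- fit_probit(cr$sus); fr <- fit_probit(cr$res)
    ff <- fit_probit(cr$f1_h1); fb <- fit_probit(cr$bc1)
    tryCatch(
      lande_effective_factors(log10(fr$lc50), log10(fs$lc50),
                              tolerance_variance(fb),
                              tolerance_variance(ff))$n_e,
      error = function(e) NA_real_)
  })
  expect_gt(median(ne, na.rm = TRUE), 0.25)
  expect_lt(median(ne, na.rm = TRUE), 0.65)
})
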