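#' Fit a probit dose-response model for one strain and compound
#'
#' Maximum-likelihood probit regression of mortality on log10 concentration
#' (via [stats::glm()] with a probit link), following the classical Finney
#' workflow: the LC50 is \eqn{10^{-b_0/b_1}}, its 95\% confidence interval
#' comes from Fieller's theorem on \eqn{-b_0/b_1}, and when the Pearson
#' goodness-of-fit chi-square exceeds its degrees of freedom the interval is
#' inflated by the heterogeneity factor and a t quantile replaces the normal
#' quantile. Control rows (concentration 0) are excluded from the fit; with
#' \code{correct_control = TRUE} treated mortalities are first
#' Abbott-corrected by the pooled control mortality.
#'
#' If pooled mortality at the highest tested concentration is below 50\%,
#' the LC50 is not interpolable and the fit is flagged \code{censored}, with
#' the top concentration reported as a lower bound (printed as e.g.
#' \code{">227"}).
#'
#' @param records Bioassay data.frame (see [read_bioassay()]) for a single
#'   strain x compound combination.
#' @param correct_control Apply Abbott's correction from pooled control
#'   rows before fitting? Default \code{FALSE}.
#' @param heterogeneity_ci Inflate the Fieller interval by the
#'   heterogeneity factor when the fit is over-dispersed? Default
#'   \code{TRUE} (the Finney convention); both behaviours are exposed.
#' @return An object of class \code{"probit_fit"}: a list with elements
#'   \code{intercept}, \code{slope}, \code{slope_se} (probit units per
#'   log10 concentration), \code{lc50}, \code{lc50_ci95}, \code{gof_chi2},
#'   \code{gof_df}, \code{heterogeneity_factor}, \code{censored},
#'   \code{n_total}, \code{strain}, \code{compound} and the underlying
#'   \code{glm}.
#' @examples
#' d <- data.frame(strain = "Sus", compound = "flubendiamide",
#'                 concentration_ug_cm2 = 0.05 * 2^(-3:4),
#'                 n_treated = 64,
#'                 n_dead = c(2, 8, 18, 32, 46, 56, 62, 64))
#' fit <- fit_probit(d)
#' fit$lc50
#' @export
fit_probit <- function(records, correct_control = FALSE,
                       heterogeneity_ci = TRUE) {
  records <- validate_bioassay(records)
  if (length(unique(records$strain)) > 1L ||
      length(unique(records$compound)) > 1L) {
    stop("fit_probit expects records for a single strain and compound; ",
         "use compare_probit_lines() or split the table", call. = FALSE)
  }
  ctrl <- records[records$concentration_ug_cm2 == 0, , drop = FALSE]
  trt <- records[records$concentration_ug_cm2 > 0, , drop = FALSE]
  doses <- sort(unique(trt$concentration_ug_cm2))
  if (length(doses) < 3L) {
    stop("need at least 3 distinct nonzero concentrations", call. = FALSE)
  }
  n_total <- sum(trt$n_treated)
  if (n_total < 30L) {
    stop("fewer than 30 treated larvae in total", call. = FALSE)
  }

  # pool replicates per concentration: same MLE, and the natural grouping
  # for the Pearson goodness-of-fit statistic
  n <- vapply(doses, function(d)
    sum(trt$n_treated[trt$concentration_ug_cm2 == d]), numeric(1))
  dead <- vapply(doses, function(d)
    sum(trt$n_dead[trt$concentration_ug_cm2 == d]), numeric(1))
  p_obs <- dead / n
  if (all(p_obs == 0) || all(p_obs == 1)) {
    stop("all-alive or all-dead at every dose: probit line not identifiable",
         call. = FALSE)
  }

  if (correct_control && nrow(ctrl) > 0L) {
    p_obs <- abbott_correct(p_obs, sum(ctrl$n_dead) / sum(ctrl$n_treated))
  }

  x <- log10(doses)
  # weighted-proportion form; identical MLE to the counts form, and it
  # accommodates Abbott-corrected (non-integer) responses
  fit <- suppressWarnings(
    stats::glm(p_obs ~ x, family = stats::binomial(link = "probit"),
               weights = n)
  )
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  b0 <- unname(b[1L]); b1 <- unname(b[2L])
  slope_se <- sqrt(V[2L, 2L])

  p_hat <- stats::pnorm(b0 + b1 * x)
  gof_df <- length(doses) - 2L
  gof_chi2 <- sum((dead - n * p_hat)^2 /
                    pmax(n * p_hat * (1 - p_hat), .Machine$double.eps))
  h <- max(gof_chi2 / gof_df, 1)

  censored <- p_obs[length(p_obs)] < 0.5
  if (censored) {
    lc50 <- max(doses)
    ci <- c(NA_real_, NA_real_)
  } else {
    m <- -b0 / b1
    lc50 <- 10^m
    ci <- 10^fieller_interval(b0, b1, V, df = gof_df,
                              heterogeneity = if (heterogeneity_ci) h else 1,
                              use_t = heterogeneity_ci && gof_chi2 > gof_df)
  }

  structure(list(
    strain = as.character(records$strain[1L]),
    compound = as.character(records$compound[1L]),
    intercept = b0, slope = b1, slope_se = slope_se,
    lc50 = lc50, lc50_ci95 = ci,
    gof_chi2 = gof_chi2, gof_df = gof_df, heterogeneity_factor = h,
    censored = censored, n_total = n_total,
    doses = doses, n = n, n_dead = dead,
    model = fit
  ), class = "probit_fit")
}

# Fieller 95% limits for m = -b0/b1 on the log10 scale (Finney's g-method).
# `heterogeneity` multiplies the variance matrix; with use_t the quantile is
# t_{0.975, df} instead of 1.96.
fieller_interval <- function(b0, b1, V, df, heterogeneity = 1,
                             use_t = FALSE) {
  q <- if (use_t) stats::qt(0.975, df) else stats::qnorm(0.975)
  v00 <- V[1L, 1L] * heterogeneity
  v01 <- V[1L, 2L] * heterogeneity
  v11 <- V[2L, 2L] * heterogeneity
  m <- -b0 / b1
  g <- q^2 * v11 / b1^2
  if (g >= 1) {
    # slope indistinguishable from zero at this confidence: unbounded CI
    return(c(-Inf, Inf))
  }
  centre <- m + g / (1 - g) * (m + v01 / v11)
  half <- q / (abs(b1) * (1 - g)) *
    sqrt(v00 + 2 * m * v01 + m^2 * v11 - g * (v00 - v01^2 / v11))
  c(centre - half, centre + half)
}

#' Predicted mortality from a probit fit
#'
#' @param fit A \code{"probit_fit"} object.
#' @param concentration Concentration(s), same units as fitted.
#' @return Predicted mortality proportion(s).
#' @export
predict_mortality <- function(fit, concentration) {
  stopifnot(inherits(fit, "probit_fit"), all(concentration > 0))
  stats::pnorm(fit$intercept + fit$slope * log10(concentration))
}

#' @export
print.probit_fit <- function(x, ...) {
  lc <- if (x$censored) paste0(">", signif(x$lc50, 3)) else
    sprintf("%s (%s-%s)", signif(x$lc50, 3),
            signif(x$lc50_ci95[1L], 3), signif(x$lc50_ci95[2L], 3))
  cat(sprintf("Probit fit: %s / %s\n", x$strain, x$compound))
  cat(sprintf("  n = %d, LC50 = %s ug a.i./cm2\n", x$n_total, lc))
  cat(sprintf("  slope = %.2f +/- %.2f, chi2 = %.2f (df = %d)\n",
              x$slope, x$slope_se, x$gof_chi2, x$gof_df))
  invisible(x)
}

#' Resistance ratio between two probit fits
#'
#' The LC50 of a test strain divided by the LC50 of the susceptible
#' reference. When the test LC50 is censored (a ">bound" fit) the ratio is
#' itself a lower bound. A censored reference leaves the ratio undefined.
#'
#' @param test A \code{"probit_fit"} or a bare LC50 value.
#' @param reference The reference \code{"probit_fit"} or LC50 value;
#'   must not be censored.
#' @return A list of class \code{"resistance_ratio"} with \code{value} and
#'   \code{is_lower_bound}.
#' @examples
#' resistance_ratio(40.4, 0.010)$value  # 4040
#' @export
resistance_ratio <- function(test, reference) {
  as_lc <- function(f) {
    if (inherits(f, "probit_fit")) list(lc50 = f$lc50, censored = f$censored)
    else list(lc50 = as.numeric(f), censored = FALSE)
  }
  a <- as_lc(test); b <- as_lc(reference)
  if (b$censored) {
    stop("reference LC50 is censored: resistance ratio undefined",
         call. = FALSE)
  }
  stopifnot(a$lc50 > 0, b$lc50 > 0)
  structure(list(value = a$lc50 / b$lc50, is_lower_bound = a$censored),
            class = "resistance_ratio")
}

#' @export
print.resistance_ratio <- function(x, ...) {
  cat(sprintf("RR = %s%s\n", if (x$is_lower_bound) ">" else "",
              signif(x$value, 4)))
  invisible(x)
}

#' Equality and parallelism tests for two probit lines
#'
#' Likelihood-ratio comparison of nested probit models for two strains:
#' the equality test contrasts a single common line against separate lines
#' (2 df); the parallelism test contrasts a common slope (separate
#' intercepts) against separate slopes (1 df). Deviance differences are
#' referred to the chi-square distribution.
#'
#' @param records_a,records_b Bioassay tables for the two strains (same
#'   compound).
#' @return A list with \code{equality_chi2}, \code{equality_df},
#'   \code{equality_p}, \code{parallelism_chi2}, \code{parallelism_df},
#'   \code{parallelism_p}.
#' @export
compare_probit_lines <- function(records_a, records_b) {
  records_a <- validate_bioassay(records_a)
  records_b <- validate_bioassay(records_b)
  ab <- rbind(
    transform(records_a[records_a$concentration_ug_cm2 > 0, ], grp = "a"),
    transform(records_b[records_b$concentration_ug_cm2 > 0, ], grp = "b")
  )
  ab$x <- log10(ab$concentration_ug_cm2)
  ab$grp <- factor(ab$grp)
  resp <- cbind(ab$n_dead, ab$n_treated - ab$n_dead)
  fam <- stats::binomial(link = "probit")
  common <- stats::glm(resp ~ x, family = fam, data = ab)
  parallel <- stats::glm(resp ~ grp + x, family = fam, data = ab)
  separate <- stats::glm(resp ~ grp * x, family = fam, data = ab)
  eq_chi2 <- max(stats::deviance(common) - stats::deviance(separate), 0)
  par_chi2 <- max(stats::deviance(parallel) - stats::deviance(separate), 0)
  list(
    equality_chi2 = eq_chi2, equality_df = 2L,
    equality_p = stats::pchisq(eq_chi2, 2L, lower.tail = FALSE),
    parallelism_chi2 = par_chi2, parallelism_df = 1L,
    parallelism_p = stats::pchisq(par_chi2, 1L, lower.tail = FALSE)
  )
}

#' Tabulate probit fits in a dose-response summary table
#'
#' @param fits A list of \code{"probit_fit"} objects.
#' @param reference Name of the reference strain for resistance ratios
#'   (ignored if absent or censored).
#' @return A data.frame with columns \code{strain}, \code{compound},
#'   \code{n}, \code{lc50}, \code{ci_low}, \code{ci_high}, \code{slope},
#'   \code{slope_se}, \code{chi2}, \code{df}, \code{rr}, \code{censored}.
#' @export
probit_table <- function(fits, reference = NULL) {
  ref <- NULL
  if (!is.null(reference)) {
    for (f in fits) {
      if (f$strain == reference && !f$censored) ref <- f
    }
  }
  do.call(rbind, lapply(fits, function(f) {
    data.frame(
      strain = f$strain, compound = f$compound, n = f$n_total,
      lc50 = f$lc50, ci_low = f$lc50_ci95[1L], ci_high = f$lc50_ci95[2L],
      slope = f$slope, slope_se = f$slope_se,
      chi2 = f$gof_chi2, df = f$gof_df,
      rr = if (!is.null(ref) && f$compound == ref$compound)
        resistance_ratio(f, ref)$value else NA_real_,
      censored = f$censored, stringsAsFactors = FALSE
    )
  }))
}
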