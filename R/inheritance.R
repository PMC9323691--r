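#' Stone's degree of dominance from LC50s
#'
#' Places the F1 log-LC50 between the parental log-LC50s on a scale from
#' -1 (completely recessive, F1 at the susceptible parent) to +1
#' (completely dominant, F1 at the resistant parent):
#' \deqn{D = \frac{2\log_{10} LC_{F1} - \log_{10} LC_R - \log_{10} LC_S}
#'            {\log_{10} LC_R - \log_{10} LC_S}.}
#' When the resistant-strain LC50 is only known as a lower bound
#' (censored fit), the value computed at the bound is an upper bound on D
#' (D falls as the true resistant LC50 exceeds the bound), reported with
#' \code{is_bound = TRUE} and printed with a \code{"<"} qualifier.
#'
#' @param lc50_sus,lc50_res,lc50_f1 LC50s of the susceptible parent, the
#'   resistant parent and the F1 cross (same units).
#' @param res_censored Is \code{lc50_res} a censored lower bound?
#' @return A list of class \code{"dominance"} with \code{method =
#'   "stone"}, \code{value} and \code{is_bound}.
#' @examples
#' stone_dominance(0.05, 227, 0.07, res_censored = TRUE)
#' @export
stone_dominance <- function(lc50_sus, lc50_res, lc50_f1,
                            res_censored = FALSE) {
  stopifnot(lc50_sus > 0, lc50_res > 0, lc50_f1 > 0)
  if (lc50_res == lc50_sus) {
    stop("parental LC50s are equal: Stone's D undefined", call. = FALSE)
  }
  ls <- log10(lc50_sus); lr <- log10(lc50_res); lf <- log10(lc50_f1)
  structure(list(method = "stone",
                 value = (2 * lf - lr - ls) / (lr - ls),
                 concentration = NA_real_,
                 is_bound = isTRUE(res_censored)),
            class = "dominance")
}

#' Bourguet's effective dominance at a fixed concentration
#'
#' Dominance of resistance expressed through genotype mortalities at one
#' dose: \eqn{D = (M_{RS} - M_{SS}) / (M_{RR} - M_{SS})}, equal to 0 when
#' the heterozygote dies like the susceptible homozygote and 1 when it
#' survives like the resistant homozygote. Sampling noise can push the raw
#' value outside \[0, 1\]; by default it is clipped to that range (the raw
#' value is always retained in \code{raw}). Equal susceptible and
#' resistant mortalities leave D undefined at that dose: an NA-valued
#' result is returned (not an error) so dose-ladder tables render with a
#' blank cell.
#'
#' @param m_ss,m_rs,m_rr Mortality percentages in \[0, 100\] of the
#'   susceptible homozygote, heterozygote (F1) and resistant homozygote.
#' @param concentration Dose at which the mortalities were observed
#'   (annotation only).
#' @param clip Clip the value to \[0, 1\]? Default \code{TRUE}.
#' @return A list of class \code{"dominance"} with \code{method =
#'   "bourguet"}, \code{value}, \code{raw}, \code{concentration},
#'   \code{is_bound = FALSE}.
#' @examples
#' bourguet_dominance(87.50, 71.35, 0.00, concentration = 0.41)$value  # 0.18
#' @export
bourguet_dominance <- function(m_ss, m_rs, m_rr, concentration = NA_real_,
                               clip = TRUE) {
  stopifnot(all(c(m_ss, m_rs, m_rr) >= 0), all(c(m_ss, m_rs, m_rr) <= 100))
  if (m_ss == m_rr) {
    return(structure(list(method = "bourguet", value = NA_real_,
                          raw = NA_real_, concentration = concentration,
                          is_bound = FALSE), class = "dominance"))
  }
  raw <- (m_rs - m_ss) / (m_rr - m_ss)
  structure(list(method = "bourguet",
                 value = if (clip) min(max(raw, 0), 1) else raw,
                 raw = raw, concentration = concentration,
                 is_bound = FALSE),
            class = "dominance")
}

#' @export
print.dominance <- function(x, ...) {
  qual <- if (isTRUE(x$is_bound)) "<" else ""
  at <- if (is.finite(x$concentration))
    sprintf(" at %g ug a.i./cm2", x$concentration) else ""
  cat(sprintf("%s dominance D = %s%s%s\n",
              if (x$method == "stone") "Stone" else "Bourguet (effective)",
              qual, formatC(x$value, format = "fg", digits = 3), at))
  invisible(x)
}

#' Classify a dominance value with a prose label
#'
#' Labels only, never used in computation: D <= -0.5 "(incompletely)
#' recessive", |D| < 0.5 "additive", D >= 0.5 "dominant".
#'
#' @param d A \code{"dominance"} object or numeric D.
#' @return A character label.
#' @export
dominance_label <- function(d) {
  v <- if (inherits(d, "dominance")) d$value else as.numeric(d)
  if (is.na(v)) return(NA_character_)
  if (v <= -0.5) "(incompletely) recessive"
  else if (v >= 0.5) "dominant" else "additive"
}

#' Mendelian expected backcross mortality
#'
#' Under monogenic resistance a backcross of F1 (RS) to the resistant
#' parent (RR) segregates 1/2 RS : 1/2 RR, so the expected mortality at a
#' dose is the mean of the F1 and resistant-strain mortalities at that
#' dose. Inputs can be observed mortalities at shared doses or
#' probit-predicted mortalities (see [monogenic_table()]).
#'
#' @param m_f1,m_res Mortality percentages in \[0, 100\].
#' @return Expected backcross mortality percentage.
#' @examples
#' backcross_expected_mortality(4.69, 0.00)  # 2.345
#' @export
backcross_expected_mortality <- function(m_f1, m_res) {
  stopifnot(all(m_f1 >= 0 & m_f1 <= 100), all(m_res >= 0 & m_res <= 100))
  (m_f1 + m_res) / 2
}

#' Monogenic-inheritance chi-square test
#'
#' Tests observed backcross mortality against the Mendelian expectation
#' with \eqn{\chi^2 = n (p_{obs} - p_{exp})^2 / (p_{exp}(1 - p_{exp}))}
#' on 1 degree of freedom — algebraically the 2-cell Pearson chi-square on
#' the (dead, alive) table with expected counts \eqn{(n p_{exp}, n(1 -
#' p_{exp}))}. Significant rows (at 0.05, \eqn{\chi^2 > 3.841}) are
#' asterisked in rendered tables.
#'
#' @param p_obs,p_exp Observed and expected mortality proportions
#'   (vectorised); \code{p_exp} strictly inside (0, 1).
#' @param n Larvae per dose group (vectorised).
#' @param concentration Optional dose annotation (vectorised).
#' @return A data.frame with \code{concentration}, \code{observed_pct},
#'   \code{expected_pct}, \code{n}, \code{chi2}, \code{p_value},
#'   \code{significant}.
#' @examples
#' monogenic_chi_square(0.3125, 0.3906, 64)$chi2  # 1.64
#' @export
monogenic_chi_square <- function(p_obs, p_exp, n,
                                 concentration = NA_real_) {
  stopifnot(all(p_obs >= 0 & p_obs <= 1), all(n >= 1))
  if (any(p_exp <= 0 | p_exp >= 1)) {
    stop("expected mortality of 0 or 1 leaves the chi-square degenerate",
         call. = FALSE)
  }
  chi2 <- n * (p_obs - p_exp)^2 / (p_exp * (1 - p_exp))
  data.frame(
    concentration = concentration,
    observed_pct = 100 * p_obs, expected_pct = 100 * p_exp,
    n = n, chi2 = chi2,
    p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE),
    significant = chi2 > stats::qchisq(0.95, 1L)
  )
}

#' Monogenic backcross test table across a dose ladder
#'
#' Builds the per-dose observed/expected/chi-square table for a backcross
#' bioassay. Expected mortality is (F1 + resistant)/2 per dose; with
#' \code{rule = "mixed"} (default) observed F1/resistant mortalities are
#' used at doses present in their bioassay tables and probit-predicted
#' mortalities elsewhere; \code{"predicted"} always predicts from the
#' fitted curves; \code{"observed"} requires every dose to be shared.
#'
#' @param bc_records Backcross bioassay table (one strain).
#' @param f1_fit,res_fit \code{"probit_fit"} objects for the F1 and the
#'   resistant strain.
#' @param f1_records,res_records Optional observed tables backing the
#'   fits, used by the mixed/observed rules.
#' @param rule Source of expected mortalities: \code{"mixed"},
#'   \code{"predicted"} or \code{"observed"}.
#' @return The [monogenic_chi_square()] data.frame, one row per dose.
#' @export
monogenic_table <- function(bc_records, f1_fit, res_fit,
                            f1_records = NULL, res_records = NULL,
                            rule = c("mixed", "predicted", "observed")) {
  rule <- match.arg(rule)
  bc_records <- validate_bioassay(bc_records)
  trt <- bc_records[bc_records$concentration_ug_cm2 > 0, , drop = FALSE]
  doses <- sort(unique(trt$concentration_ug_cm2))

  observed_at <- function(records, d) {
    if (is.null(records)) return(NA_real_)
    sub <- records[records$concentration_ug_cm2 == d, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_real_)
    sum(sub$n_dead) / sum(sub$n_treated)
  }
  source_mortality <- function(records, fit, d) {
    obs <- if (rule != "predicted") observed_at(records, d) else NA_real_
    if (!is.na(obs)) return(obs)
    if (rule == "observed") {
      stop("no observed mortality at dose ", d, call. = FALSE)
    }
    predict_mortality(fit, d)
  }

  rows <- lapply(doses, function(d) {
    sub <- trt[trt$concentration_ug_cm2 == d, , drop = FALSE]
    n <- sum(sub$n_treated)
    p_obs <- sum(sub$n_dead) / n
    p_f1 <- source_mortality(f1_records, f1_fit, d)
    p_res <- source_mortality(res_records, res_fit, d)
    p_exp <- backcross_expected_mortality(100 * p_f1, 100 * p_res) / 100
    if (p_exp <= 0 || p_exp >= 1) {
      return(data.frame(concentration = d, observed_pct = 100 * p_obs,
                        expected_pct = 100 * p_exp, n = n,
                        chi2 = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    monogenic_chi_square(p_obs, p_exp, n, concentration = d)
  })
  do.call(rbind, rows)
}

#' Lande's number of effective factors
#'
#' Estimates the number of independently segregating loci behind a
#' quantitative resistance difference from the parental phenotypic range
#' and the segregating variance released in the backcross:
#' \deqn{n_E = \frac{(\bar z_R - \bar z_S)^2}{8 \sigma^2_s},\qquad
#'       \sigma^2_s = \sigma^2_{BC} - \sigma^2_{F1},}
#' with means and variances on the log10-tolerance scale (for a probit
#' line, tolerance variance = 1/slope^2 in log10-dose units; the
#' genetically uniform F1 estimates the environmental variance).
#'
#' @param mean_log_lc_res,mean_log_lc_sus Mean log10 tolerances of the
#'   resistant and susceptible parents (log10 LC50s).
#' @param var_backcross,var_f1 Log10-tolerance variances of the backcross
#'   and F1 generations.
#' @return A list of class \code{"effective_factors"} with \code{n_e},
#'   \code{phenotypic_range} and \code{segregational_variance}.
#' @export
lande_effective_factors <- function(mean_log_lc_res, mean_log_lc_sus,
                                    var_backcross, var_f1) {
  stopifnot(var_f1 >= 0)
  sigma2_s <- var_backcross - var_f1
  if (sigma2_s <= 0) {
    stop("backcross variance does not exceed F1 variance: ",
         "no detectable segregating variance", call. = FALSE)
  }
  range <- mean_log_lc_res - mean_log_lc_sus
  structure(list(n_e = range^2 / (8 * sigma2_s),
                 phenotypic_range = range,
                 segregational_variance = sigma2_s),
            class = "effective_factors")
}

#' @export
print.effective_factors <- function(x, ...) {
  cat(sprintf(
    "Effective factors n_e = %.2f (range %.2f log10 units, sigma2_s = %.3f)\n",
    x$n_e, x$phenotypic_range, x$segregational_variance))
  invisible(x)
}

#' Tolerance variance implied by a probit slope
#'
#' On the log10-dose scale a probit line with slope b corresponds to a
#' normal tolerance distribution with standard deviation 1/b.
#'
#' @param fit A \code{"probit_fit"} object or a numeric slope.
#' @return The tolerance variance 1/slope^2.
#' @export
tolerance_variance <- function(fit) {
  b <- if (inherits(fit, "probit_fit")) fit$slope else as.numeric(fit)
  stopifnot(b != 0)
  1 / b^2
}
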