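#' Classify F2-screen isolines as positive or negative
#'
#' An isoline (the sib-mated progeny of one field-collected single-pair
#' mating) is scored positive when at least one F2 larva exposed to the
#' discriminating dose survives to the adult stage, revealing a recessive
#' resistance allele among the four alleles its grandparents contributed.
#' Isolines tested with fewer larvae than \code{min_larvae} are excluded
#' (partial screens have reduced detection power).
#'
#' @param raw A data.frame with columns \code{population}, \code{season},
#'   \code{n_larvae_tested}, \code{n_survivors_to_adult}.
#' @param min_larvae Minimum larvae tested for an isoline to count
#'   (default 64, half the 128-larva target design).
#' @return The table with a logical \code{positive} column; excluded
#'   isolines are dropped and their count attached as
#'   \code{attr(, "n_excluded")}.
#' @export
classify_isolines <- function(raw, min_larvae = 64L) {
  required <- c("population", "season", "n_larvae_tested",
                "n_survivors_to_adult")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("isoline table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(raw$n_larvae_tested < 0 | raw$n_survivors_to_adult < 0)) {
    stop("negative counts in isoline table", call. = FALSE)
  }
  if (any(raw$n_larvae_tested == 0)) {
    stop("isolines with zero larvae tested are not interpretable",
         call. = FALSE)
  }
  if (any(raw$n_survivors_to_adult > raw$n_larvae_tested)) {
    stop("more survivors than larvae tested", call. = FALSE)
  }
  keep <- raw$n_larvae_tested >= min_larvae
  out <- raw[keep, , drop = FALSE]
  out$positive <- out$n_survivors_to_adult >= 1L
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Estimate the recessive resistance-allele frequency from an F2 screen
#'
#' Each screened isoline carries 4 alleles sampled from the population,
#' so \code{n} isolines screen \code{4n} alleles. The point estimate of
#' the resistance-allele frequency is \eqn{(s + 1) / (4n)} for \code{s}
#' positive isolines, and the 95\% interval is the equal-tailed credible
#' interval of the Beta(\eqn{s + 1}, \eqn{4n - s + 1}) posterior (uniform
#' prior on the allele count among the \eqn{4n} screened alleles). The
#' point estimator and the interval come from different constructions, so
#' the point estimate is not forced to sit inside the interval.
#'
#' @param s Number of positive isolines.
#' @param n Number of isolines screened.
#' @return An object of class \code{"f2_freq"}: a list with
#'   \code{n_isolines}, \code{n_positive}, \code{alleles_screened},
#'   \code{p_hat} and \code{ci95}.
#' @examples
#' est <- estimate_frequency(13, 63)
#' round(100 * est$p_hat, 2)  # 5.56
#' @export
estimate_frequency <- function(s, n) {
  stopifnot(length(s) == 1L, length(n) == 1L)
  if (n < 1) stop("need at least one screened isoline", call. = FALSE)
  if (s < 0 || s > n) stop("need 0 <= s <= n", call. = FALSE)
  alleles <- 4 * n
  structure(list(
    n_isolines = as.integer(n),
    n_positive = as.integer(s),
    alleles_screened = as.integer(alleles),
    p_hat = (s + 1) / alleles,
    ci95 = stats::qbeta(c(0.025, 0.975), s + 1, alleles - s + 1)
  ), class = "f2_freq")
}

#' @export
print.f2_freq <- function(x, ...) {
  cat(sprintf(
    "F2 screen: %d positive of %d isolines (%d alleles)\n  p = %.4f (95%% CI %.4f-%.4f)\n",
    x$n_positive, x$n_isolines, x$alleles_screened,
    x$p_hat, x$ci95[1L], x$ci95[2L]))
  invisible(x)
}

#' Per-group and composite F2-screen frequency estimates
#'
#' Pools positive-isoline and isoline counts within each group (season by
#' default), applies [estimate_frequency()] to the pooled counts, and flags
#' group pairs whose 95\% intervals do not overlap as significantly
#' different (no multiplicity adjustment; interval non-overlap is the
#' conventional field criterion).
#'
#' @param outcomes Classified isoline table (see [classify_isolines()]).
#' @param by Grouping column, default \code{"season"}.
#' @return A list with \code{estimates} (data.frame: group, n_isolines,
#'   n_positive, p_hat, ci_low, ci_high) and \code{comparisons}
#'   (data.frame of group pairs with a \code{different} flag).
#' @export
composite_frequency <- function(outcomes, by = "season") {
  if (!by %in% names(outcomes)) {
    stop("grouping column '", by, "' not found", call. = FALSE)
  }
  groups <- unique(outcomes[[by]])
  if (length(groups) == 0L) stop("no groups to estimate", call. = FALSE)
  est <- do.call(rbind, lapply(groups, function(g) {
    sub <- outcomes[outcomes[[by]] == g, , drop = FALSE]
    e <- estimate_frequency(sum(sub$positive), nrow(sub))
    data.frame(group = g, n_isolines = e$n_isolines,
               n_positive = e$n_positive, p_hat = e$p_hat,
               ci_low = e$ci95[1L], ci_high = e$ci95[2L],
               stringsAsFactors = FALSE)
  }))
  names(est)[1L] <- by
  comparisons <- NULL
  if (nrow(est) > 1L) {
    idx <- utils::combn(nrow(est), 2L)
    comparisons <- data.frame(
      group_a = est[[by]][idx[1L, ]],
      group_b = est[[by]][idx[2L, ]],
      different = est$ci_low[idx[1L, ]] > est$ci_high[idx[2L, ]] |
        est$ci_low[idx[2L, ]] > est$ci_high[idx[1L, ]],
      stringsAsFactors = FALSE
    )
  }
  list(estimates = est, comparisons = comparisons)
}

#' Monte-Carlo power of an F2-screen design
#'
#' Simulates full screens at a given true allele frequency (via
#' [simulate_f2_screen()]) and reports the probability of detecting at
#' least one positive isoline together with the mean frequency estimate,
#' for evaluating screen designs before fieldwork.
#'
#' @param p_true True resistance-allele frequency (0 < p < 1 or exactly 0
#'   for the degenerate no-allele case).
#' @param n_isolines,n_larvae Design: isolines screened, larvae per isoline.
#' @param rr_survival Survival probability of a homozygous-resistant larva
#'   at the screen dose (1 = perfect detection).
#' @param n_sim Number of simulated screens.
#' @param seed RNG seed.
#' @return A list with \code{detection_prob} (probability that s >= 1),
#'   \code{mean_p_hat} and \code{mean_s}.
#' @export
screen_power <- function(p_true, n_isolines = 100L, n_larvae = 128L,
                         rr_survival = 1, n_sim = 500L, seed = 1L) {
  stopifnot(p_true >= 0, p_true < 1, n_sim >= 1)
  cfg <- sim_config(
    seed = seed,
    allele_freqs = c(I = 1 - p_true, M = p_true, K = 0),
    n_isolines = n_isolines, n_larvae_per_isoline = n_larvae
  )
  set.seed(seed)
  s <- numeric(n_sim)
  p_hat <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    scr <- simulate_f2_screen(cfg, seed = NULL, rr_survival = rr_survival)
    s[i] <- sum(scr$positive)
    p_hat[i] <- estimate_frequency(s[i], nrow(scr))$p_hat
  }
  list(detection_prob = mean(s >= 1), mean_p_hat = mean(p_hat),
       mean_s = mean(s))
}
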