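#' Simulation configuration for resistance-genetics study designs
#'
#' Bundles the generative parameters shared by the simulators: a single
#' autosomal biallelic resistance locus (the M and K target-site alleles
#' are phenotypically equivalent "R" by default), genotype-specific probit
#' dose-response curves, Hardy-Weinberg allele frequencies, and the
#' bioassay/screen design sizes. Defaults reproduce the reference study
#' conditions: susceptible LC50 0.05 ug a.i./cm2 with slope 1.53,
#' resistant LC50 at the 227 bound with slope 0.70, heterozygote curve
#' placed from a Stone dominance of -0.92, diagnostic dose 0.41, screen
#' dose 12.71, 128 larvae per isoline and 64 larvae per dose group.
#'
#' @param seed Integer RNG seed; identical configs (including seed) give
#'   identical outputs.
#' @param allele_freqs Named proportions for alleles I, M, K; must sum
#'   to 1.
#' @param genotype_lc50 Named LC50s for classes SS, RS, RR; a missing or
#'   NA RS entry is placed from \code{dominance_true} via the Stone
#'   relation.
#' @param genotype_slope Named probit slopes for SS, RS, RR.
#' @param dominance_true Stone D used to place the RS curve when its LC50
#'   is not given.
#' @param n_isolines,n_larvae_per_isoline F2-screen design.
#' @param dose_grid Concentrations (ug a.i./cm2) for bioassays.
#' @param n_per_dose Larvae per dose group.
#' @param control_mortality Natural mortality proportion in control wells.
#' @param diagnostic_dose,screen_dose Monitoring and F2-screen
#'   discriminating concentrations.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       allele_freqs = c(I = 0.95, M = 0.045, K = 0.005),
                       genotype_lc50 = c(SS = 0.05, RS = NA, RR = 227),
                       genotype_slope = c(SS = 1.53, RS = 1.53, RR = 0.70),
                       dominance_true = -0.92,
                       n_isolines = 100L,
                       n_larvae_per_isoline = 128L,
                       dose_grid = c(0.01, 0.02, 0.13, 0.41, 1.27, 2.27,
                                     22.7, 227),
                       n_per_dose = 64L,
                       control_mortality = 0.0208,
                       diagnostic_dose = 0.41,
                       screen_dose = 12.71) {
  stopifnot(all(c("I", "M", "K") %in% names(allele_freqs)),
            abs(sum(allele_freqs) - 1) < 1e-9,
            all(allele_freqs >= 0))
  lc <- genotype_lc50
  if (is.na(lc[["RS"]])) {
    ls <- log10(lc[["SS"]]); lr <- log10(lc[["RR"]])
    lc[["RS"]] <- 10^((dominance_true * (lr - ls) + lr + ls) / 2)
  }
  stopifnot(all(lc > 0), all(genotype_slope > 0),
            all(dose_grid > 0), n_per_dose >= 1,
            control_mortality >= 0, control_mortality < 1)
  structure(list(
    seed = as.integer(seed), allele_freqs = allele_freqs,
    genotype_lc50 = lc, genotype_slope = genotype_slope,
    dominance_true = dominance_true,
    n_isolines = as.integer(n_isolines),
    n_larvae_per_isoline = as.integer(n_larvae_per_isoline),
    dose_grid = sort(dose_grid), n_per_dose = as.integer(n_per_dose),
    control_mortality = control_mortality,
    diagnostic_dose = diagnostic_dose, screen_dose = screen_dose
  ), class = "sim_config")
}

# probit mortality of a genotype class at a dose
class_mortality <- function(config, class, dose) {
  stats::pnorm(config$genotype_slope[[class]] *
                 (log10(dose) - log10(config$genotype_lc50[[class]])))
}

#' Simulate a Hardy-Weinberg genotype panel
#'
#' Draws individuals with Hardy-Weinberg genotype probabilities from the
#' configured I/M/K allele frequencies.
#'
#' @param config A [sim_config()].
#' @param n_individuals Panel size.
#' @param population,season Labels attached to the calls.
#' @param seed RNG seed; \code{NULL} leaves the RNG state untouched
#'   (useful inside seeded loops). Defaults to the config seed.
#' @return A genotype-call data.frame (see [tabulate_genotypes()]).
#' @export
simulate_genotype_panel <- function(config, n_individuals = 20L,
                                    population = "simpop",
                                    season = "season1",
                                    seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$allele_freqs[c("I", "M", "K")]
  alleles <- names(p)
  pairs <- expand.grid(a1 = alleles, a2 = alleles,
                       stringsAsFactors = FALSE)
  probs <- p[pairs$a1] * p[pairs$a2]
  idx <- sample.int(nrow(pairs), n_individuals, replace = TRUE,
                    prob = probs)
  data.frame(
    individual_id = sprintf("%s_%04d", population, seq_len(n_individuals)),
    population = population, state = NA_character_, season = season,
    allele_1 = pairs$a1[idx], allele_2 = pairs$a2[idx],
    stringsAsFactors = FALSE
  )
}

#' Simulate a dose-response bioassay for a genotype mixture
#'
#' For each dose, larvae are allocated to genotype classes by a
#' multinomial draw on the mixture proportions and die with the class's
#' probit mortality; control wells (concentration 0) die with the
#' configured natural mortality.
#'
#' @param config A [sim_config()].
#' @param mix Named genotype-class proportions (SS, RS, RR) summing to 1.
#' @param strain,compound Labels for the records.
#' @param doses Dose grid; defaults to the config grid.
#' @param n_per_dose Larvae per dose group; defaults to the config value.
#' @param include_control Add a concentration-0 control row?
#' @param seed RNG seed (see [simulate_genotype_panel()]).
#' @return A bioassay data.frame (see [read_bioassay()]).
#' @export
simulate_bioassay <- function(config, mix = c(SS = 1, RS = 0, RR = 0),
                              strain = "Sus", compound = "flubendiamide",
                              doses = config$dose_grid,
                              n_per_dose = config$n_per_dose,
                              include_control = TRUE,
                              seed = config$seed) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, all(mix >= 0))
  if (!is.null(seed)) set.seed(seed)
  classes <- c("SS", "RS", "RR")
  mix <- mix[classes]; mix[is.na(mix)] <- 0
  rows <- lapply(doses, function(d) {
    counts <- as.vector(stats::rmultinom(1L, n_per_dose, mix))
    dead <- sum(vapply(seq_along(classes), function(i) {
      if (counts[i] == 0L) return(0L)
      stats::rbinom(1L, counts[i], class_mortality(config, classes[i], d))
    }, integer(1)))
    data.frame(strain = strain, compound = compound,
               concentration_ug_cm2 = d, n_treated = n_per_dose,
               n_dead = dead, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_control) {
    ctrl <- data.frame(strain = strain, compound = compound,
                       concentration_ug_cm2 = 0,
                       n_treated = n_per_dose,
                       n_dead = stats::rbinom(1L, n_per_dose,
                                              config$control_mortality),
                       stringsAsFactors = FALSE)
    out <- rbind(ctrl, out)
  }
  out
}

#' Simulate a full F2 screen
#'
#' Each isoline draws 4 founding alleles from the population pool (a
#' field-mated single-pair design). With k resistance alleles among the
#' 4 founders, the expected homozygous-resistant fraction in the sib-mated
#' F2 is (k/4)^2 (1/16 for a single allele). Larvae are exposed to the
#' screen dose; only RR larvae can survive, each with the RR curve's
#' survival probability at that dose (overridable for perfect-detection
#' designs). An isoline is positive when at least one larva survives.
#'
#' @param config A [sim_config()].
#' @param population,season Labels.
#' @param rr_survival Survival probability of an RR larva at the screen
#'   dose; \code{NULL} (default) computes it from the RR probit curve.
#' @param seed RNG seed (see [simulate_genotype_panel()]).
#' @return An isoline data.frame with a \code{positive} column.
#' @export
simulate_f2_screen <- function(config, population = "simpop",
                               season = "season1", rr_survival = NULL,
                               seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rr_survival)) {
    rr_survival <- 1 - class_mortality(config, "RR", config$screen_dose)
  }
  p_r <- config$allele_freqs[["M"]] + config$allele_freqs[["K"]]
  n <- config$n_isolines
  k <- stats::rbinom(n, 4L, p_r)            # founder R alleles per isoline
  rr_frac <- (k / 4)^2                      # expected Mendelian F2 fraction
  n_rr <- stats::rbinom(n, config$n_larvae_per_isoline, rr_frac)
  survivors <- stats::rbinom(n, n_rr, rr_survival)
  data.frame(
    population = population, season = season,
    n_larvae_tested = config$n_larvae_per_isoline,
    n_survivors_to_adult = survivors,
    positive = survivors >= 1L,
    stringsAsFactors = FALSE
  )
}

#' Simulate the cross and backcross bioassay tables
#'
#' Generates dose-response tables for the susceptible parent (SS), the
#' resistant parent (RR), both reciprocal F1 crosses (RS; the curve placed
#' from the configured true dominance), and both backcrosses (a 1/2 RS :
#' 1/2 RR Mendelian mixture), each at the configured dose grid and group
#' size.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (see [simulate_genotype_panel()]).
#' @return A named list of bioassay data.frames: \code{sus}, \code{res},
#'   \code{f1_h1}, \code{f1_h2}, \code{bc1}, \code{bc2}.
#' @export
simulate_crosses <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(mix, strain) {
    simulate_bioassay(config, mix = mix, strain = strain, seed = NULL)
  }
  list(
    sus   = mk(c(SS = 1, RS = 0, RR = 0), "Sus"),
    res   = mk(c(SS = 0, RS = 0, RR = 1), "R"),
    f1_h1 = mk(c(SS = 0, RS = 1, RR = 0), "H1"),
    f1_h2 = mk(c(SS = 0, RS = 1, RR = 0), "H2"),
    bc1   = mk(c(SS = 0, RS = 0.5, RR = 0.5), "BC1"),
    bc2   = mk(c(SS = 0, RS = 0.5, RR = 0.5), "BC2")
  )
}
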