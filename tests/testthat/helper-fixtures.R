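# Deterministic bioassay table with exact (noise-free) expected deaths on a
# probit line; non-integer deaths are fine for the weighted-proportion MLE.
exact_bioassay <- function(lc50, slope, doses, n = 1000,
                           strain = "S", compound = "flubendiamide") {
  p <- pnorm(slope * (log10(doses) - log10(lc50)))
  data.frame(strain = strain, compound = compound,
             concentration_ug_cm2 = doses, n_treated = n,
             n_dead = n * p, stringsAsFactors = FALSE)
}

# geometric dose ladder centred on an LC50
dose_ladder <- function(lc50, k = 8, step = 2) {
  lc50 * step^(seq_len(k) - (k + 1) / 2)
}

# genotype-call table from a named genotype count vector, e.g. c(II = 18, IM = 2)
calls_from_counts <- function(counts, population = "P") {
  a1 <- character(0); a2 <- character(0)
  for (g in names(counts)) {
    a1 <- c(a1, rep(substr(g, 1, 1), counts[[g]]))
    a2 <- c(a2, rep(substr(g, 2, 2), counts[[g]]))
  }
  data.frame(individual_id = seq_along(a1), population = population,
             allele_1 = a1, allele_2 = a2, stringsAsFactors = FALSE)
}

table2_barf_backcross <- data.frame(  # BA-R female x F1 male column, printed
  concentration = c(0.02, 0.23, 2.27, 12.71, 22.70, 227.00),
  obs_pct = c(12.5, 29.69, 31.25, 39.58, 45.83, 59.38),
  exp_pct = c(2.34, 28.9, 39.06, 47.92, 49.71, 50.5),
  chi2 = c(28.84, 0.02, 1.64, 1.78, 0.38, 2.02)
)
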