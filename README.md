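# resistkit

Quantitative genetics of insecticide resistance monitoring, built around
the workflow used to track diamide resistance in fall armyworm
(*Spodoptera frugiperda*): probit dose–response analysis, F2-screen
estimation of recessive resistance-allele frequencies, inheritance
statistics from reciprocal crosses and backcrosses, and tabulation of
ryanodine-receptor (RyR) I4790M/K target-site genotypes with
genotype–phenotype association. A seeded simulator generates every kind
of dataset the analyses consume, so the whole pipeline is testable
without field data.

## What it computes

**Probit dose–response.** For each strain × compound, mortality is
regressed on log10 concentration by maximum-likelihood probit
(`fit_probit`). The LC50 is `10^(-b0/b1)`; its 95% CI comes from
Fieller's theorem, inflated by the heterogeneity factor
`max(chi2/df, 1)` with a t quantile when the Pearson goodness-of-fit
chi-square exceeds its degrees of freedom. When the top tested dose
kills fewer than half the larvae the LC50 is reported as a censored
bound (">227"). Resistance ratios (`resistance_ratio`) divide a test
LC50 by the susceptible reference; equality and parallelism of two
probit lines are likelihood-ratio tests on 2 and 1 df
(`compare_probit_lines`).

**F2 screen.** Each isoline (offspring of one field-mated single pair)
screens 4 alleles; with `s` positive isolines among `n`, the
resistance-allele frequency is estimated as `(s + 1) / (4n)` with an
equal-tailed 95% credible interval from the Beta(s + 1, 4n − s + 1)
posterior (`estimate_frequency`, `composite_frequency`).

**Inheritance.** Stone's degree of dominance
`D = (2 log LC50_F1 − log LC50_R − log LC50_S) / (log LC50_R − log LC50_S)`
(`stone_dominance`), Bourguet's per-dose effective dominance
`D = (M_RS − M_SS)/(M_RR − M_SS)` (`bourguet_dominance`), the monogenic
backcross test `chi2 = n (p_obs − p_exp)^2 / (p_exp (1 − p_exp))`
against the Mendelian expectation `(M_F1 + M_RR)/2`
(`monogenic_chi_square`, `monogenic_table`), and Lande's effective
factor count `n_E = (Δ log LC50)^2 / (8 σ²_s)`
(`lande_effective_factors`).

**Genotyping.** `tabulate_genotypes` counts I/M/K allele pairs into
genotype and allele frequencies per population; `associate_mortality`
regresses discriminating-dose survival on resistance-allele frequency
and reports F, df, R and p.

## Worked example

```r
library(resistkit)

cfg <- sim_config(seed = 2024)        # recessive one-locus study design
crosses <- simulate_crosses(cfg)      # Sus, R, reciprocal F1s, backcrosses

sus <- fit_probit(crosses$sus)
res <- fit_probit(crosses$res)
f1  <- fit_probit(crosses$f1_h1)
sus
#> Probit fit: Sus / flubendiamide
#>   n = 512, LC50 = 0.0503 (0.0375-0.0661) ug a.i./cm2
#>   slope = 1.41 +/- 0.12, chi2 = 1.18 (df = 6)
res
#> Probit fit: R / flubendiamide
#>   n = 512, LC50 = >227 ug a.i./cm2
#>   slope = 0.59 +/- 0.07, chi2 = 3.16 (df = 6)

resistance_ratio(res, sus)
#> RR = >4516

stone_dominance(sus$lc50, res$lc50, f1$lc50, res_censored = res$censored)
#> Stone dominance D = <-0.892

estimate_frequency(13, 63)            # a real 63-isoline screen outcome
#> F2 screen: 13 positive of 63 isolines (252 alleles)
#>   p = 0.0556 (95% CI 0.0306-0.0863)
```

The simulated susceptible strain recovers its generating LC50 (0.05),
the resistant strain is censored above the top tested dose with a
resistance ratio above 4500-fold, the F1 places near the susceptible
parent (D < −0.89: incompletely recessive), and a screen with 13
positive isolines of 63 gives an allele frequency of 5.56%.

`run_pipeline(list(seed = 42, simulate = TRUE), "report/")` runs every
stage on a simulated multi-population study and writes the report
tables, a JSON results bundle and a run manifest;
`inst/scripts/resistkit.R` exposes the same stages as shell verbs.

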