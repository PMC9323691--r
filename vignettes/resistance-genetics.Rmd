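---
title: "Models and methods behind resistkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resistkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistkit)
```

resistkit implements the statistical core of a resistance-monitoring
programme for a lepidopteran pest: diet-overlay bioassays scored as
dead/alive counts per concentration, F2 screens of field-mated
isofemale lines, reciprocal crosses and backcrosses to characterise
inheritance, and target-site genotyping at the ryanodine-receptor
(RyR) 4790 position, where the I (wildtype), M and K alleles segregate.
This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where
more than one defensible construction exists.

## The probit dose-response model

Mortality at concentration $d$ (µg a.i./cm²) is modelled as
$P(\text{death}) = \Phi(b_0 + b_1 \log_{10} d)$, the classical probit
tolerance model: log tolerances are normal with mean
$-b_0/b_1 = \log_{10} LC_{50}$ and standard deviation $1/b_1$.
`fit_probit()` maximises the binomial likelihood with `stats::glm`
(probit link) on records pooled by concentration. Design
preconditions are enforced, not assumed: at least three distinct
nonzero concentrations, at least 30 treated larvae, and a response
that is not uniformly 0% or 100%.

Numerical and inferential choices:

* **Confidence limits.** Fieller's theorem on the ratio $-b_0/b_1$.
  When the Pearson goodness-of-fit $\chi^2$ over dose groups exceeds
  its $k - 2$ degrees of freedom, the variance matrix is inflated by
  the heterogeneity factor $h = \chi^2/\mathrm{df}$ and the normal
  quantile is replaced by $t_{0.975,\mathrm{df}}$ — the Finney
  convention. `heterogeneity_ci = FALSE` disables the inflation; both
  behaviours are exposed because published tables rarely state which
  was used. When Fieller's $g \ge 1$ (slope indistinguishable from 0
  at the 95% level) the interval is reported as unbounded rather than
  the misleading finite ellipse.
* **Censoring.** If pooled mortality at the highest tested
  concentration is below 50%, the LC50 is not interpolable; the fit is
  flagged `censored` and the top concentration is reported as a lower
  bound (printed `">227"`). Downstream statistics propagate the flag:
  resistance ratios become lower bounds, Stone's D an upper bound.
* **Control mortality.** Natural response is handled by an optional
  Abbott pre-correction (`correct_control = TRUE`) from the pooled
  concentration-0 rows, not by a fitted natural-response parameter.
  The default is off, matching the convention of reporting uncorrected
  control mortality alongside the dose ladder.
* **Extreme dose groups.** 0% and 100% groups stay in the likelihood
  unadjusted; they are informative under maximum likelihood (empirical
  probit corrections are a relic of the graphical method).
* **Line comparison.** `compare_probit_lines()` uses likelihood-ratio
  tests between nested binomial GLMs: common line vs separate lines
  (equality, 2 df) and common slope vs separate slopes (parallelism,
  1 df). The equality statistic therefore always dominates the
  parallelism statistic on the same pair.

## F2-screen allele-frequency estimation

An isoline founded by one field-mated pair carries 4 alleles; sib
mating the F1 exposes a recessive resistance allele, if present, in
1/16 of the F2, and a single surviving adult at the discriminating
dose scores the line positive. With $s$ positive lines of $n$:

* point estimate $\hat p = (s + 1) / (4n)$;
* 95% equal-tailed credible interval from
  $\mathrm{Beta}(s + 1,\; 4n - s + 1)$, i.e. a uniform prior on the
  allele count among the $4n$ screened alleles.

The $(s+1)/(4n)$ form is fixed deliberately: among the candidate
estimators in the F2-screen literature it is the one that reproduces
the reference screen's printed 5.56% for $s = 13, n = 63$ exactly
(the $(s+1)/(4(n+1))$ variant gives 5.47%, the posterior mean
$(s+1)/(4n+2)$ gives 5.51%). Because the point estimator and the
interval come from different constructions, the software does not
force the point estimate inside the interval (it can sit outside for
extreme $s$). Seasons are compared by interval non-overlap, with no
multiplicity adjustment — the conventional field criterion, reported
as such. Isolines screened with fewer than `min_larvae = 64` larvae
(half the 128 target) are excluded rather than down-weighted.

## Inheritance statistics

**Stone's D** scales the F1 position between parental log-LC50s to
$[-1, 1]$. It is invariant to a common rescaling of the three LC50s.
With a censored resistant LC50 the value computed at the bound is an
upper bound on D (D decreases as the true LC50 exceeds the bound) and
is printed with a `<` qualifier.

**Bourguet's effective dominance** works per concentration on
genotype mortalities, $D = (M_{RS} - M_{SS})/(M_{RR} - M_{SS})$.
Sampling noise can push raw values outside $[0,1]$; they are clipped
by default with the raw value always retained. At a concentration
where $M_{SS} = M_{RR}$ the statistic is undefined; a missing value is
returned instead of an error so that dose-ladder tables render with a
blank cell. At concentration 0 with natural mortality only in the
susceptible strain the formula gives exactly 1.

**Monogenic backcross test.** Under one-locus resistance the
backcross to the resistant parent is ½RS : ½RR, so expected mortality
is the mean of the F1 and resistant-strain mortalities at that dose.
The test statistic $n(p_{obs} - p_{exp})^2 / (p_{exp}(1 - p_{exp}))$
is algebraically the 2-cell Pearson chi-square on the (dead, alive)
table — asserted numerically over $10^5$ random inputs in the test
suite. `monogenic_table()` sources expected mortalities by a mixed
rule: observed F1/resistant mortalities at shared doses,
probit-predicted ones elsewhere (the rule that best matches published
backcross tables); `rule = "predicted"` and `"observed"` are also
available. The group size $n$ is a required input; 64 per dose is the
documented reproduction setting for the reference tables. Note the
expectation is itself estimated, so the statistic is conservative only
in name: its null distribution is inflated by roughly
$1 + (v_{F1} + v_{RR})/(4 v_{BC})$; the simulation suite verifies the
realised size stays below 10% at the 5% nominal level under the
generating monogenic model.

**Lande's effective factors.**
$n_E = (\Delta \bar z)^2 / (8 \sigma^2_s)$ with
$\sigma^2_s = \sigma^2_{BC} - \sigma^2_{F1}$, variances on the
log10-tolerance scale obtained from probit slopes
($\sigma^2 = 1/b_1^2$). Two biases are worth knowing about, and the
package documents rather than hides them: (i) the formula assumes
additive gene action — under full recessivity the backcross releases
about twice the additive segregational variance, so a true one-locus
recessive trait yields $n_E \approx 0.4$–$0.5$, not 1; (ii) the
shallow slope of a highly resistant class inflates $\sigma^2_{BC}$
further. The simulation recovery test is frozen to the closed-form
value under the generating recessive model ($\approx 0.43$), not to
the naive monogenic expectation of 1.

## Genotyping and association

Genotype calls are unordered I/M/K allele pairs; tabulation is exact
counting, invariant to row order and to swapping the two allele
columns, with `wildtype_freq + resistance_freq = 1` by construction
(M/K heterozygotes contribute both alleles to the resistance class).
The abundance ranking string covers observed genotypes only, with
separators rendered from the count ratio between neighbours (≥10× →
`>>>`, ≥3× → `>>`, else `>`); ties break lexicographically.

`associate_mortality()` regresses survival at the discriminating dose
on resistance-allele frequency across populations (ordinary least
squares), reporting $F = (n-2)r^2/(1-r^2)$ on $(1, n-2)$ df — the
square of the slope's t statistic — and $R = |r|$ with the signed
value retained. By complement symmetry, regressing mortality on
wildtype frequency gives the identical test. Populations missing from
either table are reported, never silently dropped; fewer than three
joined populations is an error.

## The simulator and what it does (not) emulate

`sim_config()` fixes the study conditions: one autosomal biallelic
locus (M and K phenotypically equivalent "R" — no allele-specific
LC50s are published), genotype-specific probit curves with the
susceptible class at LC50 0.05 µg a.i./cm² and slope 1.53, the
resistant class at the 227 bound with slope 0.70, and the heterozygote
curve placed from a true Stone D of −0.92 via the Stone relation.
Screens use 128 larvae per isoline at the 12.71 discriminating dose;
bioassays use 64 larvae per dose on a Table-style ladder; control
wells die at the 2.08% natural rate. Where a generative value had to
be chosen without a stated counterpart (the between-population spread
of allele frequencies in the simulated monitoring study), a Beta
distribution centred on the configured frequency was chosen once as a
realistic field spread and not revisited.

F2 screens draw 4 founder alleles per isoline and use the expected
Mendelian F2 RR fraction $(k/4)^2$ for $k$ founder R alleles (1/16
for a single allele) rather than an individual-by-individual pedigree;
only RR larvae can survive the screen dose. Consequences worth
noting: the simulator does not model sib-mating drift around the
expected fraction, partial penetrance, heterozygote leakage at the
screen dose, multiple paternity, or fitness costs across generations.
Passing tests therefore demonstrate estimator correctness under the
idealised single-locus recessive model, not robustness to those field
realities. One deliberate mismatch with the source programme: the
0.41 µg a.i./cm² diagnostic dose is labelled an LC99 in the
monitoring literature, but the susceptible parameters used here (and
the published susceptible dose ladder itself) put susceptible
mortality at that dose near 88–92%; the simulator keeps the published
parameters, and detection-premise checks are asserted at the 12.71
screen dose, where susceptible mortality genuinely exceeds 99.9%.

Determinism is a contract: every simulator accepts a seed (defaulting
to the config's), identical configs give byte-identical CSVs, and
`run_pipeline()` derives all stage randomness from the single
top-level seed.

## Problem sizes used in validation

The simulation-based checks run at the design sizes of the reference
study: probit recovery over 200 simulated assays of 8 doses × 64
larvae (median $|\log_{10}(\widehat{LC50}/LC50)| < 0.05$); F2-screen
interval coverage over 100 screens of 200 isolines × 128 larvae at a
true frequency of 0.045; monogenic-test size over 200 simulated cross
studies; association calibration by 500 permutations of a
62-population panel. These sizes are the package's validation choices
and match the scale of the programme it models.

## Known limitations

* Probit only; no logit or complementary log-log links, and no
  time-mortality modelling.
* The LC99-derivation pipeline for the diagnostic dose is out of
  scope; the dose is configured input.
* The F2-screen estimator assumes full recessivity, full penetrance
  and 4 independently sampled founder alleles; deviations are for
  stress-testing via the simulator, not corrected in the estimator.
* Lande's $n_E$ inherits its additivity assumption; see above.
* Genotype calling from raw fluorescence is out of scope; the input
  is the call table.
```{r session}
sessionInfo()
```
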