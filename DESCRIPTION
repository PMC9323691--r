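Package: resistkit
Title: Insecticide Resistance Genetics: Probit Dose-Response, F2 Screens
    and Target-Site Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative genetics of insecticide resistance
    monitoring: maximum-likelihood probit dose-response analysis with
    Fieller confidence limits and heterogeneity correction, resistance
    ratios and probit-line equality/parallelism tests; F2-screen
    estimation of recessive resistance-allele frequencies with Bayesian
    credible intervals; inheritance statistics (Stone and Bourguet degrees
    of dominance, the monogenic backcross chi-square test, Lande's number
    of effective factors); tabulation of ryanodine-receptor target-site
    genotypes and genotype-phenotype association; and a stochastic
    simulator of bioassays, crosses, genotype panels and F2 screens for
    design evaluation and validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
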