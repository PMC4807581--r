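Package: panelgxe
Title: Gene-Environment Interaction Analysis for Repeated-Measures Air
    Pollution Panel Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing modification of short-term air pollution
    effects on blood pressure and heart rate variability by genetic
    polymorphisms in repeated-measures (panel) studies of elderly
    populations. Implements exposure preprocessing (apparent temperature,
    distributed lags, interquartile-range scaling), genotype quality
    control (minor allele frequency, Hardy-Weinberg testing, two-locus EM
    haplotype estimation and |D'|-based pruning), single-SNP interaction
    screening in linear mixed models with AIC lag selection and a 2-df
    joint test, unweighted genetic risk scores with tertile-stratified
    effect estimation and heterogeneity testing, and an
    inverse-probability-of-follow-up-weighting sensitivity analysis. A
    synthetic-cohort generator with configurable linkage disequilibrium,
    planted interaction effects and non-random dropout makes the whole
    pipeline testable without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
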