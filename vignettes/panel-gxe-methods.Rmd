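---
title: "Methods: gene-environment interaction analysis in an air-pollution panel study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-environment interaction analysis in an air-pollution panel study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

Short-term exposure to ambient air pollution (PM10, NO2, SO2) raises blood
pressure (BP) and depresses heart rate variability (HRV) in susceptible
people, plausibly through oxidative stress. If that mechanism is real, the
exposure-response association should be stronger in people carrying more
risk alleles of oxidative-stress genes. `panelgxe` implements the analysis
that tests this in a repeated-measures (panel) design: elderly subjects are
examined up to 5 times over about two years, daily pollutant exposure is
assigned from the nearest monitor, and each subject contributes genotypes
for a few dozen candidate SNPs in oxidative-stress genes.

The package covers the whole analysis chain — exposure preprocessing,
genotype QC and linkage-disequilibrium (LD) pruning, single-SNP interaction
screening in linear mixed models, genetic risk scores (GRS) with
tertile-stratified effect estimates and a heterogeneity test, and an
inverse-probability-of-follow-up-weighting (IPW) sensitivity analysis —
plus a synthetic-cohort generator that reproduces the statistical structure
the analysis assumes, so every stage is testable without access to the
original individual-level data (which are not deposited).

# The models

## Main exposure model

For outcome $y_{ij}$ of subject $i$ at visit $j$ (SBP, DBP, MAP in mmHg;
log-SDNN, log-RMSSD, log-LF, log-HF on the natural-log scale),

$$ y_{ij} = \beta_0 + \gamma^\top c_{ij} + \beta_E x_{ij} + b_i + e_{ij},
\qquad b_i \sim N(0, \sigma_b^2),\; e_{ij} \sim N(0, \sigma_e^2), $$

where $x_{ij}$ is the pollutant concentration at the selected lag, divided
by its interquartile range (IQR) so that $\beta_E$ reads "outcome change
per IQR increase", and $c_{ij}$ are the a-priori covariates: age, sex,
smoking status (4 levels, including "did not answer"), alcohol drinking (3
levels), BMI, hypertension medication, and apparent temperature. Apparent
temperature, $-2.653 + 0.994\,T + 0.0153\,D^2$ for daily mean temperature
$T$ and dew point $D$ (deg C), enters at the same lag as the pollutant
under test (the lag convention for temperature is not pinned down by
convention in this design; using the pollutant's lag keeps the two
co-varying weather terms aligned). All covariates except BMI and apparent
temperature are time-independent baseline values.

All models are fitted by **maximum likelihood** (`lme4::lmer`,
`REML = FALSE`): AIC comparisons across fixed-effect structures (lag
selection) and likelihood-ratio tests both require ML. The random-effects
structure is a subject random intercept only; no random slopes,
autoregressive residuals or spatial terms are fitted (the analysis model
mirrors what repeated-measures panel studies of this size support).

## Lag selection

Single-day lags 0-3 are candidate exposure windows. For each
outcome-pollutant pair the four lag variants are fitted **on the identical
complete-case observation set** (rows complete for all four lags) and the
minimum-AIC lag wins, ties going to the smallest lag. Selection is done
once per outcome-pollutant pair on the main model and reused for all SNP
models of that pair; selecting per-SNP would let the lag wander across
models of the same association and invite overfitting.

## Interaction screening

Each SNP enters additively (minor-allele count 0/1/2). The interaction
model adds the SNP and its product with the scaled pollutant to the main
model; the default "P for interaction" is the Wald test of the product
coefficient (a 1-df LRT is available as an option). A SNP is
*interaction-positive* for an outcome family (BP: SBP/DBP/MAP; HRV: the
four log outcomes) when any of its family tests has $p < \alpha$ with
$\alpha = 0.05$ and no multiplicity correction — the screen is
hypothesis-generating, and the downstream GRS aggregates rather than
certifies individual SNPs.

The **risk allele** is defined by the interaction's direction: the minor
allele is the risk allele when the interaction points adverse — positive
for BP outcomes, negative for log-HRV outcomes. When a SNP is
interaction-positive in several tests, its orientation is inherited from
the single smallest-p interaction within the family.

A **2-df joint test** (sensitivity analysis) compares the full ML model
(SNP + interaction) with a nested model excluding both SNP terms by LRT on
the identical observation set, referred to $\chi^2_2$; the code refuses the
comparison if the two observation sets differ.

## Genotype QC and LD pruning

Per SNP: minor allele frequency (re-oriented so MAF $\le 0.5$) and a 1-df
Pearson chi-square Hardy-Weinberg test at the sample allele frequency.
SNPs with HWE $p <$ 0.001 are excluded (the default catches violations of
the magnitude that motivates exclusion in practice while leaving ordinary
sampling noise alone; configurable).

Pairwise $|D'|$ within each gene is computed from unphased genotypes by the
standard two-locus EM: all genotype pairs except double heterozygotes have
unambiguous haplotype composition; double heterozygotes split fractionally
between the AB/ab and Ab/aB phases in proportion to current frequency
products. The EM starts from linkage-equilibrium products and, because the
likelihood can be bimodal in $f_{AB}$ when double heterozygotes are
present, also from both disequilibrium boundaries, keeping the
best-likelihood solution; convergence is a maximum frequency change below
1e-8 (at most 1000 iterations), and the log-likelihood is checked to be
non-decreasing. Pairs with $|D'| > 0.8$ are linked; blocks are connected
components of the within-gene link graph (cross-gene pairs never merge),
and one SNP per block is retained — by default the member with the
smallest single-SNP interaction p-value, ties to listed order. The 0.8
threshold is a configuration default, not a claim about the original
analysis, which reports only the pruned pairs ($|D'| \ge 0.93$), not its
cutoff. An "other member" rule builds the alternative panel used to check
that GRS conclusions do not hinge on which block representative was kept.

## Genetic risk scores and stratification

The GRS is the **unweighted** sum of risk alleles over the pruned panel
(weighted scores are deliberately not offered: there is no agreed way to
weight heterogeneous interaction effects). Scores are split at their
empirical 1/3 and 2/3 quantiles (inverse-ECDF, "type 1", so cutpoints are
attained scores); ties go to the lower group, which yields contiguous
integer bands such as "12-13". Subjects missing any panel genotype get a
missing score by default (mean imputation per SNP is an option).

Within each tertile the main exposure model is refitted, **with the IQR
fixed at its whole-cohort value** so per-IQR estimates are comparable
across strata. Heterogeneity is tested by adding the ordinal tertile score
(0/1/2) and its product with the scaled pollutant to the main model (Wald
test on the product term; a 2-df categorical variant is available).

## IPW for non-random follow-up

Retention of each planned visit $v \ge 2$ (given visit $v-1$ was observed)
is modelled by logistic regression on the prior visit's age, sex, BMI,
years of schooling, SBP, season (calendar quarter) and daily mean outdoor
temperature. First observations get weight 1; observed follow-ups get
$1/\hat p$ with $\hat p$ clipped below at 0.01 to bound the weights
(stabilization is unnecessary at this clip level for monotone dropout over
4 transitions). Weights are per-visit inverse probabilities, matching the
"weight of 1 to the first observation, inverse probability to each
follow-up" construction; cumulative-product weights would be the
alternative reading and can be built by multiplying the per-visit
probabilities along each subject's history. The weighted mixed models use
observation-level frequency-type weights in the likelihood — an
approximation to the weighted-GEE formulation that is exact for the point
estimate contrast of interest here and keeps the estimator inside the same
ML machinery as every other fit.

# The synthetic cohort

The generator reproduces the *statistical structure* the analysis assumes,
with defaults fixed at the study's published margins:

* **Cohort**: 547 subjects, 5 planned visits evenly spaced over ~700 days
  with +/-14-day uniform jitter (the design says only "up to 5 surveys"
  over two years; spacing and jitter are exposed as parameters).
* **Covariates**: age ~ N(70.7, 5.2) floored at 60; 73.9% women; smoking
  5.5/6.6/85.4/2.6% (current/ex/non/no answer); alcohol 21.6/75.3/3.1%;
  BMI ~ N(24.7, 3) with +/-0.5 visit-level wobble. Joint distribution is
  independent — no joint table is published. Hypertension medication (35%)
  and schooling years (ordinal 0-16, mode ~6) are not tabulated in the
  source; the values are plausible for an elderly urban Korean cohort and
  fixed once.
* **Exposures**: stationary AR(1) pollutants with marginal mean/SD
  PM10 42.6 (24.7), NO2 36.5 (12.6), SO2 4.0 (2.1), day-to-day
  autocorrelation 0.5-0.6, floored at 0.1 unit so IQR scaling stays
  defined (flooring, not truncation-resampling, keeps the mean within the
  published value); temperature and dew point follow an annual sinusoid
  (means 16.9 and 6.2, amplitudes 12 and 14, noise SD 3.5 and 4) peaking
  at day-of-year 212.
* **Genotypes**: 47 SNPs in 18 oxidative-stress genes. Published rs
  numbers are used where the screening results name them; the rest are
  clearly synthetic (`syn_*`) padding, and gene assignments and MAFs
  (0.08-0.45) are illustrative. Four within-gene LD pairs are generated
  from two-SNP haplotype frequencies constructed to the reported
  $|D'|$ values (0.98, 0.93, 1.0, 0.94); one SNP (rs2965753) is planted
  out of HWE via the inbreeding model $P(\mathrm{het}) = 2pq(1-f)$ with
  $f = 0.3$ — large enough that the exclusion rule catches it essentially
  always at $n = 547$, which is the point of planting it.
* **Outcomes**: the generating model *is* the analysis model (random
  intercept, per-IQR exposure effect at a true lag, optional per-risk-allele
  interaction), so parameter recovery is a meaningful check. HRV outcomes
  are generated on the log scale and stored as positive raw values;
  variance components match the published geometric SDs. SBP is clamped to
  at least DBP + 1 in the rare tail (~0.1% of rows) where the two
  independently generated pressures would cross. An optional subject-level
  random slope on the scaled pollutant (with configurable correlation to
  the random intercept) supports the dropout scenario below.
* **Dropout**: monotone; the first visit is always kept and each later
  visit is retained with probability expit(linear predictor) evaluated on
  the previous visit's row. Mechanisms: none, MCAR, MAR on prior-visit
  columns (including outcomes such as prior SBP).

What the generator does **not** emulate: spatial monitor assignment (one
series for the cohort — mean monitor distance was under 1 km), genotyping
error, joint covariate structure, measurement-occasion effects, or
non-monotone (intermittent) missingness. Passing tests therefore show the
estimators do what they claim under the assumed data-generating structure,
not that the original data meet those assumptions.

## The two headline simulation scenarios

`scenario_hrv_modification()`: ten unlinked SNPs carry an interaction of
-0.03 log-SDNN per IQR per risk allele. With a zero pollutant main effect
the cohort-level slope would be $\beta_{int}\,\bar G \ne 0$, so the main
effect is set to $-\beta_{int} E[G]$, cancelling the marginal association
at the mean risk score. The result is the signature the stratified
analysis exists to expose: a null whole-cohort association hiding
opposite-signed effects in the extreme GRS tertiles.

`scenario_ipw_dropout()`: dropout depending only on *observed prior-visit*
variables is MAR and ignorable for a correctly specified ML mixed model,
so no such scenario can bias the unweighted fit — weighting would then be
a coin flip. Realistic bias needs (mild) model misspecification: the
scenario gives subjects heterogeneous per-IQR slopes (SD 2 mmHg/IQR,
correlation 0.7 with the BP random intercept), while the analysis model
fits a common slope. Dropout tied to prior SBP (logit slope -0.05/mmHg,
~75% retention per visit at the mean) then preferentially removes
high-slope subjects, biasing the unweighted estimate low; the follow-up
model, which includes prior BP, recovers the selection and weighting pulls
the estimate back toward the population value.

# Numerical choices and degenerate inputs

* Quantiles: IQRs use linear interpolation (type 7); tertile cutpoints use
  inverse-ECDF (type 1) so cutpoints are attained integer scores.
* Wald CIs are estimate +/- 1.96 SE; AIC is `2k - 2 logLik` at the ML fit.
* A single available BP reading is used as-is with a warning (exclusion is
  reserved for subjects with *no* reading).
* Natural log (not log10) for HRV; inference is invariant to the base.
* Zero-IQR exposures, monomorphic SNPs, fewer than 3 distinct GRS values,
  all-observed follow-up, and coverage gaps in the exposure series are
  rejected with specific errors rather than propagated; monomorphic SNPs
  in an analysis sample are skipped with a log message.
* `lmer` runs with `calc.derivs = FALSE` (the analytic linear-mixed-model
  solutions do not need finite-difference derivatives) and singular-fit
  checks off, since $\sigma_b = 0$ boundary fits are legitimate in the
  simulations; convergence failures still abort the fit.
* Negative 2-df LRT statistics beyond -1e-6 abort (non-nested fits); small
  negative values from optimizer noise clamp to 0.

# Problem sizes used by the test suite

The statistical suites run at the sizes a desk check supports, chosen as
the package's own verification design: null calibration of the interaction
Wald test and 2-df LRT with 1000 outcome redraws on a fixed 500 x 5
design (size must land in [0.035, 0.065] at nominal 0.05); CI coverage of
a planted 2 mmHg/IQR/allele interaction over 300 redraws (93-97%
required); the tertile sign-flip signature over 100 full simulations of
547 subjects (>= 90% required); IPW bias reduction over 200 simulations of
500 subjects (>= 70% required). Outcome redraws reuse one simulated design
and `lme4::refit`, which is exact for these checks (the tests condition on
the design, as the estimators themselves do) and keeps the whole suite in
a few minutes.

# Known limitations

* The default SNP panel's gene assignments and MAFs are partly synthetic;
  identities of HRV-panel blocks are reproduced by procedure, not by
  published identity.
* Frequency-type weights in weighted `lmer` are an approximation to
  weighted GEE; robust (sandwich) standard errors for the weighted fits
  are not provided.
* Two-locus EM only; no multi-SNP haplotype phasing, no r-squared or
  confidence-interval block definitions — the pruning follows pairwise
  $|D'|$ exclusively.
* Single-pollutant models only; multi-pollutant co-adjustment is out of
  scope.
* Smooth (spline) exposure-response visualisation within tertiles is out
  of scope; the stratified linear estimates carry the inferential content.
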