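## Scenario specification objects for the synthetic cohort generator.

#' Specify one biallelic SNP for simulation
#'
#' @param snp_id Character id (e.g. an rs number).
#' @param gene Gene symbol the SNP belongs to; linkage-disequilibrium blocks
#'   are only ever formed within a gene.
#' @param maf Minor allele frequency, in (0, 0.5]. Genotyping panels in this
#'   setting are restricted to common variants (MAF >= 5 percent), which is
#'   the default lower bound a scenario should respect.
#' @param hwe_violation If `TRUE`, genotypes at this SNP are drawn out of
#'   Hardy-Weinberg equilibrium using the inbreeding-coefficient model
#'   `P(het) = 2pq(1 - f)`.
#' @param f Inbreeding coefficient used when `hwe_violation` is `TRUE`.
#' @return An object of class `snp_spec`.
#' @export
snp_spec <- function(snp_id, gene, maf, hwe_violation = FALSE, f = 0.3) {
  if (!is.character(snp_id) || length(snp_id) != 1L)
    stop_cfg("snp_id must be a single string")
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop_cfg("maf for %s must lie in (0, 0.5], got %s", snp_id, maf)
  if (hwe_violation && (f <= 0 || f >= 1))
    stop_cfg("inbreeding coefficient f must lie in (0, 1)")
  structure(list(snp_id = snp_id, gene = gene, maf = maf,
                 hwe_violation = isTRUE(hwe_violation), f = f),
            class = "snp_spec")
}

#' Specify a linkage-disequilibrium block by its haplotype frequencies
#'
#' A block of k SNPs in the same gene is simulated by drawing two haplotypes
#' per subject from the `2^k` haplotype frequencies. Haplotypes are labelled
#' by binary strings (`"11"`, `"10"`, ... for k = 2) where `1` denotes the
#' minor allele at that position.
#'
#' @param gene Gene symbol; all member SNPs must be assigned to it.
#' @param snp_ids Ordered character vector (length >= 2) of member SNP ids.
#' @param haplotype_freqs Named numeric vector of length `2^k` over the
#'   binary haplotype labels; must sum to 1.
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(gene, snp_ids, haplotype_freqs) {
  k <- length(snp_ids)
  if (k < 2L) stop_cfg("an LD block needs at least 2 SNPs")
  labs <- haplotype_labels(k)
  if (is.null(names(haplotype_freqs)) ||
      !setequal(names(haplotype_freqs), labs))
    stop_cfg("haplotype_freqs must be named by the %d binary labels", 2^k)
  haplotype_freqs <- haplotype_freqs[labs]
  if (any(haplotype_freqs < 0) || abs(sum(haplotype_freqs) - 1) > 1e-12)
    stop_cfg("haplotype_freqs must be non-negative and sum to 1 (got %.15f)",
             sum(haplotype_freqs))
  structure(list(gene = gene, snp_ids = snp_ids,
                 haplotype_freqs = haplotype_freqs),
            class = "ld_block_spec")
}

haplotype_labels <- function(k) {
  g <- expand.grid(rep(list(c("1", "0")), k))[, k:1, drop = FALSE]
  apply(g, 1, paste0, collapse = "")
}

## Marginal minor-allele frequency of member j implied by block frequencies.
block_marginal_maf <- function(block, j) {
  labs <- names(block$haplotype_freqs)
  sum(block$haplotype_freqs[substr(labs, j, j) == "1"])
}

#' Construct two-SNP haplotype frequencies with a target |D'|
#'
#' Convenience builder for [ld_block_spec()]: given the two minor allele
#' frequencies and a target `|D'|`, returns the four haplotype frequencies
#' (labels `"11", "10", "01", "00"`) with positive disequilibrium
#' `D = d_prime_target * Dmax`, `Dmax = min(p1 (1 - p2), (1 - p1) p2)`.
#'
#' @param p1,p2 Minor allele frequencies at the two loci.
#' @param d_prime_target Target `|D'|` in `[0, 1]`.
#' @return Named numeric vector of four haplotype frequencies.
#' @export
ld_pair_haplotypes <- function(p1, p2, d_prime_target) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            d_prime_target >= 0, d_prime_target <= 1)
  dmax <- min(p1 * (1 - p2), (1 - p1) * p2)
  D <- d_prime_target * dmax
  c("11" = p1 * p2 + D, "10" = p1 * (1 - p2) - D,
    "01" = (1 - p1) * p2 - D, "00" = (1 - p1) * (1 - p2) + D)
}

#' Specify the generating model for one outcome
#'
#' The synthetic outcome for subject i at visit j is
#' `y_ij = intercept + covariate effects + beta_main * x_ij +
#'  sum_s beta_int * g_is * x_ij + b_i + s_i * x_ij + e_ij`,
#' where `x_ij` is the pollutant at the true lag scaled to its IQR over the
#' visit days, `g_is` the risk-allele count at planted SNP s, `b_i` a normal
#' random intercept and `e_ij` normal residual noise. HRV outcomes are
#' generated on the natural-log scale and stored as positive raw values.
#'
#' @param outcome One of `"sbp"`, `"dbp"`, `"sdnn"`, `"rmssd"`, `"lf"`, `"hf"`.
#' @param pollutant One of `"pm10"`, `"no2"`, `"so2"`.
#' @param intercept Outcome intercept (log scale for HRV outcomes).
#' @param main_effect Pollutant main effect, outcome units per IQR.
#' @param interaction_per_risk_allele Interaction effect, outcome units per
#'   IQR per risk allele.
#' @param interacting_snps `data.frame(snp_id, orientation)` with orientation
#'   `"minor_is_risk"` or `"major_is_risk"`; `NULL` for none.
#' @param covariate_effects Named numeric vector of coefficients on covariate
#'   columns (e.g. `c(age = 0.2)`); applied to the raw covariate values.
#' @param random_intercept_sd,residual_sd Standard deviations of `b_i`, `e_ij`
#'   (must be >= 0).
#' @param true_lag Lag (days, 0-3) at which the pollutant acts.
#' @param random_slope_sd Optional SD of a subject-level deviation `s_i` in
#'   the per-IQR pollutant slope (0 = homogeneous slope).
#' @param slope_intercept_cor Correlation between `b_i` and `s_i`.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(outcome, pollutant = "pm10", intercept = 0,
                        main_effect = 0, interaction_per_risk_allele = 0,
                        interacting_snps = NULL, covariate_effects = NULL,
                        random_intercept_sd = 1, residual_sd = 1,
                        true_lag = 0, random_slope_sd = 0,
                        slope_intercept_cor = 0) {
  outcome <- match.arg(outcome, c("sbp", "dbp", "sdnn", "rmssd", "lf", "hf"))
  pollutant <- match.arg(pollutant, c("pm10", "no2", "so2"))
  if (!true_lag %in% 0:3) stop_cfg("true_lag must be in 0..3")
  if (random_intercept_sd < 0 || residual_sd < 0 || random_slope_sd < 0)
    stop_cfg("standard deviations must be >= 0")
  if (abs(slope_intercept_cor) > 1) stop_cfg("|slope_intercept_cor| <= 1")
  if (!is.null(interacting_snps)) {
    stopifnot(is.data.frame(interacting_snps),
              all(c("snp_id", "orientation") %in% names(interacting_snps)),
              all(interacting_snps$orientation %in%
                    c("minor_is_risk", "major_is_risk")))
  }
  structure(list(outcome = outcome, pollutant = pollutant,
                 intercept = intercept, main_effect = main_effect,
                 interaction_per_risk_allele = interaction_per_risk_allele,
                 interacting_snps = interacting_snps,
                 covariate_effects = covariate_effects,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd, true_lag = true_lag,
                 random_slope_sd = random_slope_sd,
                 slope_intercept_cor = slope_intercept_cor),
            class = "effect_spec")
}

#' Specify the loss-to-follow-up mechanism
#'
#' @param mechanism `"none"` (all planned visits observed), `"MCAR"`
#'   (retention probability from the intercept only), or `"MAR"` (retention
#'   probability from the prior visit's covariates).
#' @param logit_coefficients Named numeric vector: `intercept` plus
#'   coefficients on prior-visit covariate columns of the panel (e.g.
#'   `c(intercept = 2, bmi = -0.1, sbp = -0.02)`). Required (non-empty beyond
#'   the intercept) for `"MAR"`.
#' @return An object of class `dropout_spec`.
#' @export
dropout_spec <- function(mechanism = c("none", "MCAR", "MAR"),
                         logit_coefficients = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "MAR") {
    covs <- setdiff(names(logit_coefficients), "intercept")
    if (length(covs) == 0)
      stop_cfg("MAR dropout requires covariate logit_coefficients")
  }
  if (mechanism == "MCAR" && is.null(logit_coefficients))
    logit_coefficients <- c(intercept = 0)
  structure(list(mechanism = mechanism,
                 logit_coefficients = logit_coefficients),
            class = "dropout_spec")
}

#' Default 47-SNP oxidative-stress panel
#'
#' A synthetic stand-in for a 47-SNP genotyping panel over 18 oxidative
#' stress genes. It uses published rs numbers for the SNPs that appear in
#' the screening and risk-score results together with clearly synthetic ids
#' (`syn_*`) as padding; gene assignments and minor allele frequencies are
#' illustrative, not looked up, and one SNP (rs2965753) is planted out of
#' Hardy-Weinberg equilibrium so the exclusion rule has something to catch.
#'
#' @return List of [snp_spec()] objects, length 47.
#' @export
default_snp_panel <- function() {
  tab <- default_snp_table()
  lapply(seq_len(nrow(tab)), function(i)
    snp_spec(tab$snp_id[i], tab$gene[i], tab$maf[i],
             hwe_violation = tab$hwe_violation[i]))
}

default_snp_table <- function() {
  known <- data.frame(
    snp_id = c("rs4646421", "rs4646422", "rs1801133", "rs2917670",
               "rs1437135", "rs2066853", "rs4680", "rs854560", "rs5277",
               "rs769218", "rs769217", "rs1799983", "rs2853796", "rs7830",
               "rs2234922", "rs1695", "rs2855658", "rs10012", "rs1800566",
               "rs3745274", "rs1799931", "rs662", "rs2758331", "rs2227956",
               "rs1051740", "rs2965753"),
    gene = c("CYP1A1", "CYP1A1", "MTHFR", "MPO", "MPO", "AhR", "COMT",
             "PON1", "PTGS2", "CAT", "CAT", "NOS3", "NOS3", "NOS3",
             "EPHX1", "GSTP1", "GSTP1", "CYP1B1", "NQO1", "CYP2B6",
             "NAT2", "PON1", "SOD2", "HSPA1L", "EPHX1", "ANKK1"),
    stringsAsFactors = FALSE)
  genes18 <- c("AhR", "ANKK1", "CAT", "COMT", "CYP1A1", "CYP1B1", "CYP2B6",
               "EPHX1", "GSTP1", "HSPA1L", "MPO", "MTHFR", "NAT2", "NOS3",
               "NQO1", "PON1", "PTGS2", "SOD2")
  pad_genes <- rep(genes18, length.out = 21)
  pad <- data.frame(snp_id = sprintf("syn_%s_%02d", pad_genes, seq_len(21)),
                    gene = pad_genes, stringsAsFactors = FALSE)
  tab <- rbind(known, pad)
  ## deterministic common-variant MAFs spread over [0.08, 0.45]
  tab$maf <- round(0.08 + 0.37 * ((seq_len(nrow(tab)) * 19) %% 29) / 29, 3)
  tab$hwe_violation <- tab$snp_id == "rs2965753"
  tab
}

#' Default linkage-disequilibrium blocks
#'
#' Four two-SNP within-gene blocks matching the pairwise `|D'|` values the
#' screening stage is expected to detect (0.98, 0.93, 1.0, 0.94).
#'
#' @param snps List of [snp_spec()] (defaults to [default_snp_panel()]);
#'   member MAFs are taken from it.
#' @return List of [ld_block_spec()] objects.
#' @export
default_ld_blocks <- function(snps = default_snp_panel()) {
  maf_of <- function(id) {
    for (s in snps) if (s$snp_id == id) return(s$maf)
    stop_cfg("block member %s not in SNP panel", id)
  }
  mk <- function(gene, a, b, dp)
    ld_block_spec(gene, c(a, b),
                  ld_pair_haplotypes(maf_of(a), maf_of(b), dp))
  list(mk("CYP1A1", "rs4646422", "rs4646421", 0.98),
       mk("MPO", "rs1437135", "rs2917670", 0.93),
       mk("CAT", "rs769218", "rs769217", 1.0),
       mk("NOS3", "rs1799983", "rs2853796", 0.94))
}

#' Printed blood-pressure screening candidates and their LD pairs
#'
#' The 15 SNPs reported as interaction-positive for blood pressure together
#' with the four within-gene LD pairs (and their reported `|D'|`) that reduce
#' them to an 11-SNP risk-score panel under one-SNP-per-block pruning.
#'
#' @return List with `candidates` (15 SNP ids), `retained` (the 11 ids kept
#'   in the published panel) and `pairs` (`data.frame(gene, snp_a, snp_b,
#'   d_prime)`).
#' @export
bp_screen_reference <- function() {
  list(
    candidates = c("rs4646421", "rs4646422", "rs1801133", "rs2917670",
                   "rs1437135", "rs2066853", "rs4680", "rs854560", "rs5277",
                   "rs769218", "rs769217", "rs1799983", "rs2853796",
                   "rs7830", "rs2234922"),
    retained = c("rs4646421", "rs1801133", "rs2917670", "rs2066853",
                 "rs4680", "rs854560", "rs5277", "rs769218", "rs1799983",
                 "rs7830", "rs2234922"),
    pairs = data.frame(
      gene = c("CYP1A1", "MPO", "CAT", "NOS3"),
      snp_a = c("rs4646422", "rs1437135", "rs769218", "rs1799983"),
      snp_b = c("rs4646421", "rs2917670", "rs769217", "rs2853796"),
      d_prime = c(0.98, 0.93, 1.0, 0.94),
      stringsAsFactors = FALSE))
}
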