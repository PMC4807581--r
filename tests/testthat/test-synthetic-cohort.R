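test_that("genotype frequencies follow Hardy-Weinberg at the specified MAF", {
  g <- simulate_genotypes(100000, list(snp_spec("s1", "G", 0.5)), seed = 1)
  freq <- tabulate(g$genotypes[, "s1"] + 1L, 3) / 100000
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 0.01))

  g2 <- simulate_genotypes(50000, list(snp_spec("s2", "G", 0.2)), seed = 2)
  expect_lt(abs(mean(g2$genotypes[, "s2"]) / 2 - 0.2), 0.005)
})

test_that("HWE-conforming SNPs pass the HWE test in almost all replicates", {
  spec <- list(snp_spec("s1", "G", 0.3))
  pass <- vapply(1:200, function(r) {
    g <- simulate_genotypes(1000, spec, seed = r)
    cnt <- tabulate(g$genotypes[, "s1"] + 1L, 3)
    hwe_test(cnt)$p >= 0.001
  }, TRUE)
  expect_gte(mean(pass), 0.99)
})

test_that("planted HWE violation produces a heterozygote deficit", {
  g <- simulate_genotypes(
    5000, list(snp_spec("s1", "G", 0.3, hwe_violation = TRUE, f = 0.3)),
    seed = 5)
  cnt <- tabulate(g$genotypes[, "s1"] + 1L, 3)
  ## P(het) = 2pq(1 - f) = 0.42 * 0.7 = 0.294
  expect_lt(abs(cnt[2] / 5000 - 0.294), 0.02)
  expect_lt(hwe_test(cnt)$p, 1e-10)
})

test_that("LD blocks reproduce the |D'| implied by their haplotype frequencies", {
  snps <- list(snp_spec("a", "G", 0.3), snp_spec("b", "G", 0.3))
  ## complete LD: haplotypes concentrated on AB and ab
  blk <- ld_block_spec("G", c("a", "b"),
                       c("11" = 0.3, "10" = 0, "01" = 0, "00" = 0.7))
  g <- simulate_genotypes(5000, snps, list(blk), seed = 3)
  em <- em_haplotype_freqs(g$genotypes[, "a"], g$genotypes[, "b"])
  expect_lt(abs(d_prime(em$freqs) - 1), 0.02)

  ## intermediate LD
  blk2 <- ld_block_spec("G", c("a", "b"),
                        ld_pair_haplotypes(0.3, 0.3, 0.6))
  g2 <- simulate_genotypes(5000, snps, list(blk2), seed = 4)
  em2 <- em_haplotype_freqs(g2$genotypes[, "a"], g2$genotypes[, "b"])
  expect_lt(abs(d_prime(em2$freqs) - 0.6), 0.05)
})

test_that("block configuration errors are caught", {
  snps <- list(snp_spec("a", "G", 0.3), snp_spec("b", "G", 0.3))
  expect_error(
    simulate_genotypes(10, snps, list(
      ld_block_spec("G", c("a", "zz"),
                    c("11" = 0.3, "10" = 0, "01" = 0, "00" = 0.7)))),
    "unknown snp_id")
  ## haplotype frequencies imply maf 0.4, spec says 0.3
  expect_error(
    simulate_genotypes(10, snps, list(
      ld_block_spec("G", c("a", "b"), ld_pair_haplotypes(0.4, 0.3, 0.5)))),
    "imply maf")
  expect_error(ld_block_spec("G", c("a", "b"),
                             c("11" = 0.5, "10" = 0.5, "01" = 0.2,
                               "00" = -0.2)),
               "sum to 1|non-negative")
})

test_that("exposure series match their specified marginal distributions", {
  s <- simulate_exposure_series(2000, seed = 10)
  expect_lt(abs(mean(s$pm10) - 42.6), 2)
  expect_lt(abs(sd(s$pm10) - 24.7), 2)
  expect_true(all(s$pm10 >= 0.1))
  expect_true(all(diff(s$date) == 1))

  ## zero sd, zero autocorrelation -> constant at the mean
  cst <- simulate_exposure_series(
    50, pollutant_params = list(pm10 = list(mean = 40, sd = 0, ar = 0),
                                no2 = list(mean = 30, sd = 0, ar = 0),
                                so2 = list(mean = 4, sd = 0, ar = 0)),
    seed = 1)
  expect_true(all(cst$pm10 == 40))

  ## AR(1) autocorrelation is recovered
  s2 <- simulate_exposure_series(
    2000, pollutant_params = list(pm10 = list(mean = 100, sd = 10, ar = 0.7),
                                  no2 = list(mean = 36.5, sd = 12.6, ar = 0.6),
                                  so2 = list(mean = 4, sd = 2.1, ar = 0.6)),
    seed = 11)
  r1 <- cor(s2$pm10[-1], s2$pm10[-2000])
  expect_lt(abs(r1 - 0.7), 0.05)
  expect_error(simulate_exposure_series(
    10, pollutant_params = list(pm10 = list(mean = 1, sd = -1, ar = 0),
                                no2 = list(mean = 1, sd = 1, ar = 0),
                                so2 = list(mean = 1, sd = 1, ar = 0))),
    "sd must be")
})

test_that("covariate marginals match the cohort's enrollment table", {
  cv <- simulate_covariates(547, seed = 20)
  expect_lt(abs(mean(cv$sex == "female") - 0.739), 0.05)
  expect_lt(abs(mean(cv$age) - 70.7), 1)
  expect_lt(abs(mean(cv$smoking == "non-smoker") - 0.854), 0.05)
  expect_lt(abs(mean(cv$bmi) - 24.7), 0.5)
  expect_true(all(cv$age >= 60))
})

test_that("null generating model yields residual-only outcome variance", {
  eff <- list(sbp = effect_spec("sbp", "pm10", intercept = 100,
                                main_effect = 0, random_intercept_sd = 0,
                                residual_sd = 5))
  sim <- simulate_study(n_subjects = 400, seed = 7, effects = eff)
  expect_lt(abs(var(sim$panel$sbp) - 25), 3)
})

test_that("planted interaction effects shift outcomes per risk allele", {
  sim <- planted_interaction_study()
  ## slope of sbp on scaled pm10 should increase with genotype
  g <- sim$genotypes$genotypes[, "rs4680"]
  p <- sim$apanel
  p$g <- g[p$subject_id]
  slopes <- vapply(0:2, function(k) {
    d <- p[p$g == k, ]
    coef(lm(sbp ~ I(pm10_lag0 / 25), data = d))[2]
  }, 0)
  expect_gt(slopes[3], slopes[1])
})

test_that("identical seeds give bit-identical simulations", {
  a <- simulate_study(n_subjects = 60, seed = 99)
  b <- simulate_study(n_subjects = 60, seed = 99)
  expect_identical(a$panel, b$panel)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)
  expect_identical(a$exposures, b$exposures)
  c <- simulate_study(n_subjects = 60, seed = 100)
  expect_false(identical(a$panel$sbp, c$panel$sbp))
})

test_that("dropout mechanisms behave as specified", {
  sim <- small_study()
  ## none -> identity
  expect_identical(apply_dropout(sim$panel, dropout_spec("none"), 1),
                   sim$panel)
  ## intercept-only logit at 0 -> about half of second visits retained
  big <- simulate_study(n_subjects = 400, seed = 13)
  kept <- apply_dropout(big$panel, dropout_spec("MCAR", c(intercept = 0)),
                        seed = 2)
  second <- sum(kept$visit == 2) / 400
  expect_lt(abs(second - 0.5), 0.06)
  ## first visits always retained; dropout monotone
  expect_equal(sum(kept$visit == 1), 400)
  by_subj <- split(kept$visit, kept$subject_id)
  expect_true(all(vapply(by_subj, function(v) all(v == seq_along(v)), TRUE)))
  ## MAR on BMI: retained subjects at visit 2 have higher BMI
  mar <- apply_dropout(big$panel,
                       dropout_spec("MAR", c(intercept = -12, bmi = 0.5)),
                       seed = 3)
  v2 <- big$panel[big$panel$visit == 2, ]
  retained <- v2$subject_id %in% mar$subject_id[mar$visit == 2]
  expect_gt(mean(v2$bmi[retained]), mean(v2$bmi[!retained]))
  ## MAR with no covariates is a configuration error
  expect_error(dropout_spec("MAR", c(intercept = 1)), "requires covariate")
})
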