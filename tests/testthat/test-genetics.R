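test_that("minor allele frequency re-orients to the minor allele", {
  g <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  expect_equal(minor_allele_frequency(g)$maf, 0.5)
  g2 <- c(rep(0L, 90), rep(1L, 10))
  expect_equal(minor_allele_frequency(g2), list(maf = 0.05, flipped = FALSE))
  g3 <- rep(2L, 100)
  out <- minor_allele_frequency(g3)
  expect_equal(out$maf, 0)
  expect_true(out$flipped)
  expect_error(minor_allele_frequency(c(NA_integer_, NA_integer_)),
               "all genotypes missing")
})

test_that("HWE chi-square matches hand-computed values", {
  out <- hwe_test(c(25, 50, 25))
  expect_equal(out$chisq, 0)
  expect_equal(out$p, 1)
  out2 <- hwe_test(c(50, 0, 50))
  expect_equal(out2$chisq, 100)   # expected (25, 50, 25): 25 + 50 + 25
  expect_lt(out2$p, 1e-20)
  out3 <- hwe_test(c(36, 48, 16)) # exact HWE at q = 0.4
  expect_equal(out3$chisq, 0, tolerance = 1e-12)
  mono <- hwe_test(c(100, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)
})

test_that("HWE test agrees with an independent textbook computation", {
  set.seed(17)
  for (i in 1:1000) {
    cnt <- rmultinom(1, sample(20:500, 1), runif(3, 0.05, 1))[, 1]
    q <- (2 * cnt[3] + cnt[2]) / (2 * sum(cnt))
    if (q == 0 || q == 1) next
    e <- sum(cnt) * c((1 - q)^2, 2 * q * (1 - q), q^2)
    ref <- sum((cnt - e)^2 / e)   # Pearson chi-square, 1 df
    expect_equal(hwe_test(cnt)$chisq, ref, tolerance = 1e-9)
  }
})

test_that("HWE exclusion removes violating SNPs only", {
  set.seed(8)
  mat <- cbind(ok = rbinom(600, 2, 0.3),
               bad = sample(0:2, 600, TRUE, prob = c(0.55, 0.10, 0.35)))
  rownames(mat) <- sprintf("S%03d", 1:600)
  tab <- toy_genotypes(mat)
  out <- apply_hwe_exclusion(tab, alpha = 0.001)
  expect_equal(out$excluded$snp_id, "bad")
  expect_equal(colnames(out$table$genotypes), "ok")
  ## alpha = 0 excludes nothing
  none <- apply_hwe_exclusion(tab, alpha = 0)
  expect_equal(nrow(none$excluded), 0)
  expect_warning(apply_hwe_exclusion(
    toy_genotypes(mat[, "bad", drop = FALSE]), alpha = 0.001),
    "all SNPs excluded")
})

test_that("EM resolves unambiguous phase in one effective step", {
  a <- c(rep(0L, 30), rep(2L, 20))
  em <- em_haplotype_freqs(a, a)
  expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
  expect_equal(unname(em$freqs[c("AB", "ab")]), c(0.4, 0.6),
               tolerance = 1e-9)
  expect_equal(as.numeric(d_prime(em$freqs)), 1)
  expect_lte(em$n_iter, 2)
  ## log-likelihood never decreases
  expect_true(all(diff(em$loglik_trace) > -1e-9))
})

test_that("EM recovers independence for unlinked SNPs", {
  set.seed(31)
  a <- rbinom(5000, 2, 0.35)
  b <- rbinom(5000, 2, 0.2)
  em <- em_haplotype_freqs(a, b)
  pa <- mean(a) / 2; pb <- mean(b) / 2
  expect_lt(abs(em$freqs[["AB"]] - pa * pb), 0.01)
  expect_lt(d_prime(em$freqs), 0.15)
})

test_that("|D'| matches hand computations and is label-invariant", {
  expect_equal(d_prime(c(0.5, 0, 0, 0.5)), 1)
  expect_equal(d_prime(c(0.25, 0.25, 0.25, 0.25)), 0)
  ## D = 0.72 - 0.64 = 0.08, Dmax = 0.16
  expect_equal(d_prime(c(0.72, 0.08, 0.08, 0.12)), 0.5)
  mono <- d_prime(c(0.7, 0.3, 0, 0))
  expect_equal(as.numeric(mono), 0)
  expect_true(attr(mono, "monomorphic"))
  set.seed(12)
  for (i in 1:50) {
    f <- runif(4); f <- f / sum(f)
    dp <- d_prime(f)
    expect_gte(dp, 0); expect_lte(dp, 1)
    ## swap loci: (AB, Ab, aB, ab) -> (AB, aB, Ab, ab)
    expect_equal(d_prime(f[c(1, 3, 2, 4)]), dp, tolerance = 1e-12)
    ## relabel alleles at locus 1: A <-> a
    expect_equal(d_prime(f[c(3, 4, 1, 2)]), dp, tolerance = 1e-12)
    ## relabel alleles at locus 2
    expect_equal(d_prime(f[c(2, 1, 4, 3)]), dp, tolerance = 1e-12)
  }
})

test_that("within-gene blocks form by connected components above threshold", {
  ref <- bp_screen_reference()
  genes <- c("CYP1A1", "CYP1A1", "MTHFR", "MPO", "MPO", "AhR", "COMT",
             "PON1", "PTGS2", "CAT", "CAT", "NOS3", "NOS3", "NOS3",
             "EPHX1")
  blocks <- blocks_from_pairs(ref$candidates, genes, ref$pairs,
                              threshold = 0.8)
  sizes <- sort(unname(vapply(blocks, function(b) length(b$members), 0L)))
  expect_equal(sizes, c(rep(1L, 7), rep(2L, 4)))
  ## below threshold: all singletons
  weak <- ref$pairs; weak$d_prime <- 0.3
  b2 <- blocks_from_pairs(ref$candidates, genes, weak, threshold = 0.8)
  expect_equal(length(b2), 15)
  ## cross-gene pairs are never merged
  xg <- data.frame(gene = "CYP1A1", snp_a = "rs4646421", snp_b = "rs4680",
                   d_prime = 1)
  b3 <- blocks_from_pairs(c("rs4646421", "rs4680"), c("CYP1A1", "COMT"),
                          xg, threshold = 0.8)
  expect_equal(length(b3), 2)
})

test_that("pruning keeps one SNP per block, with both representative rules", {
  ref <- bp_screen_reference()
  genes <- c("CYP1A1", "CYP1A1", "MTHFR", "MPO", "MPO", "AhR", "COMT",
             "PON1", "PTGS2", "CAT", "CAT", "NOS3", "NOS3", "NOS3",
             "EPHX1")
  blocks <- blocks_from_pairs(ref$candidates, genes, ref$pairs, 0.8)
  ## a stat favouring the published picks recovers them exactly
  stat <- setNames(ifelse(ref$candidates %in% ref$retained, 0.01, 0.04),
                   ref$candidates)
  kept <- prune_blocks(ref$candidates, blocks, stat = stat)
  expect_setequal(kept, ref$retained)
  ## the alternative panel has the same size and differs at each pair
  alt <- alternative_panel(ref$candidates, blocks, stat = stat)
  expect_equal(length(alt), 11)
  expect_equal(sum(!alt %in% kept), 4)
  ## all-singleton blocks: identity
  solo <- blocks_from_pairs(c("x", "y"), c("A", "B"),
                            data.frame(gene = character(),
                                       snp_a = character(),
                                       snp_b = character(),
                                       d_prime = numeric()), 0.8)
  expect_equal(prune_blocks(c("x", "y"), solo), c("x", "y"))
  expect_error(prune_blocks("zz", blocks), "belongs to no block")
})
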