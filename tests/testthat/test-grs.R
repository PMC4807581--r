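test_that("cohort exclusions are applied sequentially and reported", {
  roster <- data.frame(
    subject_id = sprintf("P%03d", 1:560),
    has_bp = c(rep(FALSE, 7), rep(TRUE, 553)),
    has_hrv = c(rep(TRUE, 7), rep(FALSE, 6), rep(TRUE, 547)))
  out <- apply_exclusions(roster)
  expect_equal(out$report$n_enrolled, 560)
  expect_equal(out$report$exclusions$count, c(7, 6))
  expect_equal(out$report$n_analyzed, 547)
  expect_equal(nrow(out$roster), 547)
  ## identity when nothing is missing
  full <- data.frame(subject_id = "a", has_bp = TRUE, has_hrv = TRUE)
  expect_equal(apply_exclusions(full)$report$n_analyzed, 1)
  ## everyone lacking BP
  empty <- data.frame(subject_id = c("a", "b"), has_bp = FALSE,
                      has_hrv = TRUE)
  expect_warning(out0 <- apply_exclusions(empty), "no subjects remain")
  expect_equal(out0$report$n_analyzed, 0)
})

test_that("risk scores sum risk alleles with orientation", {
  mat <- rbind(S1 = c(a = 0L, b = 0L), S2 = c(a = 2L, b = 0L))
  gt <- toy_genotypes(mat)
  pan <- data.frame(snp_id = c("a", "b"),
                    orientation = c("minor_is_risk", "minor_is_risk"))
  expect_equal(unname(compute_grs(gt, pan)$score), c(0, 2))
  ## genotype 0 at a major_is_risk SNP contributes 2
  pan2 <- data.frame(snp_id = c("a", "b"),
                     orientation = c("minor_is_risk", "major_is_risk"))
  expect_equal(unname(compute_grs(gt, pan2)$score), c(2, 4))
  ## maximum score is 2K
  matk <- matrix(2L, 3, 11,
                 dimnames = list(paste0("S", 1:3), paste0("s", 1:11)))
  pank <- data.frame(snp_id = paste0("s", 1:11),
                     orientation = "minor_is_risk")
  expect_equal(unname(compute_grs(toy_genotypes(matk), pank)$score),
               rep(22, 3))
  expect_error(compute_grs(gt, pan[0, ]), "empty SNP panel")
})

test_that("GRS is invariant under simultaneous recode and orientation flip", {
  set.seed(3)
  mat <- matrix(rbinom(200, 2, 0.3), 20, 10,
                dimnames = list(sprintf("S%02d", 1:20), paste0("s", 1:10)))
  pan <- data.frame(snp_id = paste0("s", 1:10),
                    orientation = sample(c("minor_is_risk", "major_is_risk"),
                                         10, TRUE))
  s1 <- compute_grs(toy_genotypes(mat), pan)$score
  mat2 <- mat; mat2[, "s3"] <- 2L - mat2[, "s3"]
  pan2 <- pan
  pan2$orientation[3] <- setdiff(c("minor_is_risk", "major_is_risk"),
                                 pan$orientation[3])
  s2 <- compute_grs(toy_genotypes(mat2), pan2)$score
  expect_identical(s1, s2)
  ## missing genotype: complete-case by default, imputable on request
  mat3 <- mat; mat3[1, 2] <- NA
  g3 <- compute_grs(toy_genotypes(mat3), pan)
  expect_true(is.na(g3$score[1]))
  expect_false(anyNA(compute_grs(toy_genotypes(mat3), pan,
                                 impute = "mean")$score))
})

test_that("tertile assignment yields contiguous integer bands", {
  s <- rep(1:9, 30)
  names(s) <- sprintf("S%03d", seq_along(s))
  t1 <- assign_tertiles(s)
  expect_equal(t1$cutpoints, c(3, 6))
  expect_equal(as.integer(table(t1$tertile)), rep(90L, 3))
  expect_equal(unname(t1$bands), c("1-3", "4-6", "7-9"))
  ## groups partition all scored subjects
  expect_equal(sum(table(t1$tertile)), length(s))
  ## integer scores with ties: bands stay contiguous
  set.seed(9)
  s2 <- rbinom(547, 22, 0.5)
  names(s2) <- sprintf("S%03d", seq_along(s2))
  t2 <- assign_tertiles(s2)
  b <- lapply(levels(t2$tertile), function(g) range(s2[t2$tertile == g]))
  expect_lt(b[[1]][2], b[[2]][1])
  expect_lt(b[[2]][2], b[[3]][1])
  expect_error(assign_tertiles(rep(5, 50)), ">= 3 distinct")
})

test_that("a single stratum containing everyone reproduces the main fit", {
  sim <- small_study()
  tert <- factor(rep("low", length(unique(sim$panel$subject_id))),
                 levels = c("low", "moderate", "high"))
  names(tert) <- unique(sim$panel$subject_id)
  sp <- model_spec("sbp", "pm10", lag = 0)
  st <- stratified_association(sim$apanel, tert, sp)
  f <- fit_main_model(sim$apanel, sp)
  expect_equal(st$estimate[1], f$estimate, tolerance = 1e-9)
  expect_equal(st$n_obs[1], f$n_obs)
  expect_true(all(is.na(st$estimate[2:3])))
})

test_that("stratified estimates reproduce a planted tertile sign flip", {
  sc <- scenario_hrv_modification()
  sim <- simulate_study(n_subjects = 547, seed = 77, effects = sc$effects)
  ap <- prepare_analysis_panel(sim$panel, sim$exposures,
                               pollutants = "pm10")
  sp <- model_spec("log_sdnn", "pm10", lag = 0)
  grs <- compute_grs(sim$genotypes, sc$panel)
  tert <- assign_tertiles(grs$score)
  st <- stratified_association(ap, tert$tertile, sp)
  expect_lt(st$estimate[st$tertile == "high"],
            st$estimate[st$tertile == "low"])
  het <- heterogeneity_test(ap, tert$tertile, sp)
  expect_lt(het$p_heterogeneity, 0.05)
  expect_lt(het$estimate, 0)
  ## 2-df categorical version agrees qualitatively
  het2 <- heterogeneity_test(ap, tert$tertile, sp, ordinal = FALSE)
  expect_lt(het2$p_heterogeneity, 0.05)
})

test_that("orientations are inherited from the screen's best interaction", {
  sc <- planted_screen()
  ori <- screen_orientations(sc, "blood_pressure")
  expect_equal(ori$orientation[ori$snp_id == "rs4680"], "minor_is_risk")
  expect_setequal(ori$snp_id, sc$bp_snps)
})
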