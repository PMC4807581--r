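## Genotype QC and linkage disequilibrium: MAF, Hardy-Weinberg chi-square,
## two-locus EM haplotype frequencies, |D'|, within-gene blocks, pruning.

#' Minor allele frequency of one genotype column
#'
#' @param g Integer vector of coded-allele counts (0/1/2, `NA` allowed).
#' @return List with `maf` (frequency of the coded allele, re-oriented so
#'   `maf <= 0.5`) and `flipped` (`TRUE` when the coded allele was actually
#'   the major allele).
#' @export
minor_allele_frequency <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) stop_cfg("all genotypes missing")
  if (!all(g %in% 0:2)) stop_cfg("genotypes must be coded 0/1/2")
  f <- sum(g) / (2 * length(g))
  if (f > 0.5) list(maf = 1 - f, flipped = TRUE)
  else list(maf = f, flipped = FALSE)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square comparing observed genotype
#' counts with `n (p^2, 2pq, q^2)` at the sample allele frequency.
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` (counts by coded-allele
#'   dose 0, 1, 2).
#' @return List with `chisq`, `p`, and `monomorphic` (if the SNP is
#'   monomorphic no test is possible and `p = 1` is returned flagged).
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop_cfg("no genotypes")
  q <- (2 * counts[3] + counts[2]) / (2 * n)
  if (q == 0 || q == 1)
    return(list(chisq = 0, p = 1, monomorphic = TRUE))
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Per-SNP quality-control summary
#'
#' @param table A `genotype_table`.
#' @return `data.frame(snp_id, gene, maf, maf_flipped, hwe_chisq, hwe_p,
#'   monomorphic)`.
#' @export
snp_qc <- function(table) {
  g <- table$genotypes
  res <- lapply(colnames(g), function(id) {
    col <- g[, id]
    maf <- minor_allele_frequency(col)
    cnt <- c(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
             sum(col == 2, na.rm = TRUE))
    hwe <- hwe_test(cnt)
    data.frame(snp_id = id, maf = maf$maf, maf_flipped = maf$flipped,
               hwe_chisq = hwe$chisq, hwe_p = hwe$p,
               monomorphic = hwe$monomorphic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$gene <- table$snp_info$gene[match(out$snp_id, table$snp_info$snp_id)]
  out[, c("snp_id", "gene", "maf", "maf_flipped", "hwe_chisq", "hwe_p",
          "monomorphic")]
}

#' Exclude SNPs failing Hardy-Weinberg equilibrium
#'
#' @param table A `genotype_table`.
#' @param alpha Exclusion threshold on the HWE p-value (default 0.001;
#'   SNPs with `hwe_p < alpha` are removed).
#' @return List with `table` (filtered `genotype_table`), `excluded`
#'   (`data.frame(snp_id, hwe_p)`) and `qc` (full QC table).
#' @export
apply_hwe_exclusion <- function(table, alpha = 0.001) {
  qc <- snp_qc(table)
  drop <- qc$snp_id[qc$hwe_p < alpha]
  if (length(drop) == ncol(table$genotypes))
    warning("all SNPs excluded by the HWE filter")
  keep <- setdiff(colnames(table$genotypes), drop)
  out <- structure(
    list(genotypes = table$genotypes[, keep, drop = FALSE],
         snp_info = table$snp_info[table$snp_info$snp_id %in% keep, ,
                                   drop = FALSE]),
    class = "genotype_table")
  list(table = out,
       excluded = qc[qc$snp_id %in% drop, c("snp_id", "hwe_p")],
       qc = qc)
}

## Genotype-pair cell probabilities given haplotype frequencies
## f = (f_AB, f_Ab, f_aB, f_ab); cells indexed [dose_a + 1, dose_b + 1].
two_locus_cell_probs <- function(f) {
  fAB <- f[1]; fAb <- f[2]; faB <- f[3]; fab <- f[4]
  matrix(c(fab^2,        2 * fab * faB,        faB^2,
           2 * fab * fAb, 2 * (fAB * fab + fAb * faB), 2 * faB * fAB,
           fAb^2,        2 * fAb * fAB,        fAB^2),
         3, 3, byrow = TRUE)
}

two_locus_loglik <- function(f, counts) {
  pr <- two_locus_cell_probs(f)
  used <- counts > 0
  if (any(pr[used] <= 0)) return(-Inf)
  sum(counts[used] * log(pr[used]))
}

#' Two-locus haplotype frequencies by EM from unphased genotypes
#'
#' Estimates the four haplotype frequencies (AB, Ab, aB, ab; capital =
#' coded/minor allele) from unphased diplotype data. All genotype pairs
#' except double heterozygotes have unambiguous haplotype composition;
#' double heterozygotes are split fractionally between AB/ab and Ab/aB in
#' the E-step in proportion to the current frequency products. Frequencies
#' are initialised at linkage-equilibrium products of the observed allele
#' frequencies and iterated until the largest absolute frequency change
#' falls below `tol`. The log-likelihood is non-decreasing across
#' iterations.
#'
#' @param geno_a,geno_b Paired genotype vectors (0/1/2); rows with a missing
#'   value in either SNP are dropped (pairwise-complete).
#' @param tol Convergence tolerance on frequencies (default 1e-8).
#' @param max_iter Maximum EM iterations (default 1000).
#' @return List with `freqs` (named, sums to 1), `loglik`, `n_iter`,
#'   `loglik_trace`, `n` (subjects used).
#' @export
em_haplotype_freqs <- function(geno_a, geno_b, tol = 1e-8, max_iter = 1000) {
  ok <- !is.na(geno_a) & !is.na(geno_b)
  a <- geno_a[ok]; b <- geno_b[ok]
  if (length(a) < 2) stop_cfg("need >= 2 subjects non-missing at both SNPs")
  counts <- matrix(0, 3, 3)
  for (i in seq_along(a)) counts[a[i] + 1, b[i] + 1] <-
      counts[a[i] + 1, b[i] + 1] + 1
  n <- length(a)
  pA <- (2 * sum(counts[3, ]) + sum(counts[2, ])) / (2 * n)
  pB <- (2 * sum(counts[, 3]) + sum(counts[, 2])) / (2 * n)
  ndh <- counts[2, 2]
  run_em <- function(f) {
    trace <- two_locus_loglik(f, counts)
    for (it in seq_len(max_iter)) {
      denom <- f[1] * f[4] + f[2] * f[3]
      w <- if (denom > 0) f[1] * f[4] / denom else 0.5
      cAB <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + w * ndh
      cAb <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1] + (1 - w) * ndh
      caB <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3] + (1 - w) * ndh
      cab <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + w * ndh
      fnew <- c(cAB, cAb, caB, cab) / (2 * n)
      delta <- max(abs(fnew - f))
      f <- fnew
      trace <- c(trace, two_locus_loglik(f, counts))
      if (delta < tol)
        return(list(freqs = f, loglik = trace[length(trace)], n_iter = it,
                    loglik_trace = trace, n = n))
    }
    stop_cfg(paste0("EM did not converge in %d iterations; last freqs: ",
                    paste(signif(f, 6), collapse = " ")), max_iter)
  }
  ## With double heterozygotes present the likelihood can be bimodal in
  ## f_AB, so EM is started from linkage equilibrium and from both
  ## disequilibrium boundaries; the best-likelihood solution is kept.
  mk <- function(fab) c(fab, pA - fab, pB - fab, 1 - pA - pB + fab)
  starts <- list(mk(pA * pB))
  if (ndh > 0) {
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    starts <- c(starts, list(mk(lo + 0.98 * (hi - lo)),
                             list(mk(lo + 0.02 * (hi - lo)))[[1]]))
  }
  fits <- lapply(starts, run_em)
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  names(best$freqs) <- c("AB", "Ab", "aB", "ab")
  best
}

#' Normalised linkage disequilibrium |D'|
#'
#' `D = f_AB - p_A p_B`; `D' = D / Dmax` with
#' `Dmax = min(p_A q_B, q_A p_B)` when `D > 0` and
#' `min(p_A p_B, q_A q_B)` when `D < 0`. Returns `|D'|` in `[0, 1]`; if
#' either locus is monomorphic the value 0 is returned with attribute
#' `monomorphic = TRUE`.
#'
#' @param freqs Haplotype frequencies `(f_AB, f_Ab, f_aB, f_ab)`.
#' @return `|D'|`.
#' @export
d_prime <- function(freqs) {
  stopifnot(length(freqs) == 4, all(freqs >= -1e-12),
            abs(sum(freqs) - 1) < 1e-6)
  pA <- freqs[1] + freqs[2]
  pB <- freqs[1] + freqs[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(structure(0, monomorphic = TRUE))
  D <- freqs[1] - pA * pB
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  unname(min(abs(D / dmax), 1))
}

#' Pairwise |D'| for all within-gene SNP pairs
#'
#' @param table A `genotype_table`.
#' @return `data.frame(gene, snp_a, snp_b, d_prime)` using pairwise-complete
#'   subjects for each pair.
#' @export
ld_pairs_within_genes <- function(table) {
  info <- table$snp_info
  out <- list()
  for (gene in unique(info$gene)) {
    ids <- info$snp_id[info$gene == gene]
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        em <- em_haplotype_freqs(table$genotypes[, ids[i]],
                                 table$genotypes[, ids[j]])
        out[[length(out) + 1]] <- data.frame(
          gene = gene, snp_a = ids[i], snp_b = ids[j],
          d_prime = as.numeric(d_prime(em$freqs)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), snp_a = character(),
                      snp_b = character(), d_prime = numeric()))
  do.call(rbind, out)
}

#' Form LD blocks from a pairwise |D'| table
#'
#' Pairs with `|D'|` above the threshold are linked; blocks are the
#' connected components of the within-gene link graph; SNPs with no link
#' form singleton blocks. Cross-gene pairs are never linked.
#'
#' @param snp_ids All SNP ids under consideration.
#' @param genes Gene of each SNP (same length).
#' @param pairs `data.frame(gene, snp_a, snp_b, d_prime)`.
#' @param threshold `|D'|` cutoff (a pair is linked when `d_prime >
#'   threshold`); default 0.8.
#' @return List of blocks, each `list(gene, members)`.
#' @export
blocks_from_pairs <- function(snp_ids, genes, pairs, threshold = 0.8) {
  stopifnot(length(snp_ids) == length(genes))
  idx <- setNames(seq_along(snp_ids), snp_ids)
  parent <- seq_along(snp_ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gene_of <- setNames(genes, snp_ids)
  link <- pairs[pairs$d_prime > threshold, , drop = FALSE]
  for (r in seq_len(nrow(link))) {
    a <- link$snp_a[r]; b <- link$snp_b[r]
    if (!a %in% snp_ids || !b %in% snp_ids) next
    if (gene_of[[a]] != gene_of[[b]]) next
    pa <- find(idx[[a]]); pb <- find(idx[[b]])
    if (pa != pb) parent[pb] <- pa
  }
  roots <- vapply(seq_along(snp_ids), find, 0L)
  lapply(split(snp_ids, roots), function(members)
    list(gene = unname(gene_of[[members[1]]]), members = unname(members)))
}

#' Find within-gene LD blocks of a genotype table
#'
#' Computes all within-gene pairwise `|D'|` values via [em_haplotype_freqs()]
#' and groups linked SNPs into blocks.
#'
#' @param table A `genotype_table`.
#' @param threshold `|D'|` cutoff (default 0.8).
#' @return List with `blocks` (see [blocks_from_pairs()]) and `pairs` (the
#'   `|D'|` table).
#' @export
find_ld_blocks <- function(table, threshold = 0.8) {
  pairs <- ld_pairs_within_genes(table)
  blocks <- blocks_from_pairs(table$snp_info$snp_id, table$snp_info$gene,
                              pairs, threshold)
  list(blocks = blocks, pairs = pairs)
}

#' Prune candidates to one SNP per LD block
#'
#' @param candidates SNP ids to prune (e.g. the interaction-positive set).
#' @param blocks List of blocks from [blocks_from_pairs()]; every candidate
#'   must belong to exactly one block.
#' @param stat Optional named numeric over SNP ids (e.g. the single-SNP
#'   interaction p-value); with `rule = "best_stat"` the member with the
#'   smallest value is retained (ties broken by listed order).
#' @param rule `"best_stat"` (default; falls back to listed order when
#'   `stat` is `NULL`), `"first"` (listed order), or `"other_member"` (the
#'   member the primary rule would *not* pick — the alternative panel used
#'   to check robustness of risk-score results).
#' @return Character vector of retained SNP ids (one per block intersecting
#'   the candidate list), in candidate order.
#' @export
prune_blocks <- function(candidates, blocks, stat = NULL,
                         rule = c("best_stat", "first", "other_member")) {
  rule <- match.arg(rule)
  membership <- integer(0)
  for (bi in seq_along(blocks)) {
    for (m in blocks[[bi]]$members) {
      if (m %in% names(membership))
        stop_cfg("SNP %s belongs to more than one block", m)
      membership[m] <- bi
    }
  }
  miss <- setdiff(candidates, names(membership))
  if (length(miss)) stop_cfg("candidate %s belongs to no block", miss[1])
  pick_primary <- function(members) {
    if (!is.null(stat) && rule != "first") {
      s <- stat[members]
      s[is.na(s)] <- Inf
      members[which.min(s)]   # which.min takes the first on ties
    } else members[1]
  }
  retained <- character(0)
  seen <- integer(0)
  for (id in candidates) {
    bi <- membership[[id]]
    if (bi %in% seen) next
    seen <- c(seen, bi)
    members <- intersect(blocks[[bi]]$members, candidates)
    primary <- pick_primary(members)
    retained <- c(retained,
                  if (rule == "other_member" && length(members) > 1)
                    setdiff(members, primary)[1] else primary)
  }
  retained
}
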