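# SNP filtering and statistics, kinship, REML and the Q+K scan.

make_gt <- function(calls, pos = NULL, chrom = "Chr1") {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  n <- nrow(calls)
  genotype_table(
    data.frame(snp_id = sprintf("s%03d", seq_len(n)),
               chrom = rep_len(chrom, n),
               pos = if (is.null(pos)) seq_len(n) * 100L else pos,
               allele_a = rep_len("A", n), allele_b = rep_len("G", n),
               stringsAsFactors = FALSE),
    calls)
}

test_that("SNP filters use strict MAF and call-rate boundaries", {
  # 10 individuals: AA x8, AB x1, NA x1 -> MAF 1/18, call rate 0.9
  gt <- make_gt(rbind(c(rep("AA", 8), "AB", NA)))
  st <- snp_stats(gt)
  expect_equal(st$maf, 1 / 18)
  expect_equal(st$call_rate, 0.9)
  expect_equal(nrow(filter_snps(gt)$snps), 1L)
  # MAF exactly 0.05: 20 individuals, 2 of 40 alleles minor
  gt2 <- make_gt(rbind(c(rep("AA", 18), "AB", "AB")))
  expect_equal(snp_stats(gt2)$maf, 0.05)
  expect_equal(nrow(filter_snps(gt2)$snps), 0L)
  # call rate exactly 0.80 fails the strict filter
  gt3 <- make_gt(rbind(c(rep("AB", 8), NA, NA)))
  expect_equal(snp_stats(gt3)$call_rate, 0.8)
  expect_equal(nrow(filter_snps(gt3)$snps), 0L)
  # empty table passes through without error
  expect_equal(nrow(filter_snps(make_gt(matrix("AA", 1, 4)[0, , drop = FALSE]))$snps), 0L)
})

test_that("heterozygosity and MAF are invariant to allele relabeling", {
  calls <- c("AA", "AB", "BB", "AB", NA)
  swapped <- c("BB", "AB", "AA", "AB", NA)
  expect_equal(observed_heterozygosity(calls),
               observed_heterozygosity(swapped))
  expect_equal(observed_heterozygosity(c("AB", "AB")), 1.0)
  expect_equal(observed_heterozygosity(c("AA", "AA", "AA", "AB")), 0.25)
  expect_error(observed_heterozygosity(c(NA, NA)), "missing")
  st1 <- snp_stats(make_gt(rbind(calls)))
  st2 <- snp_stats(make_gt(rbind(swapped)))
  expect_equal(st1$maf, st2$maf)
  expect_equal(st1$het, st2$het)
})

test_that("SNPs are located in loci with exon/intron context", {
  ts <- tiny_transcripts(list(
    list(id = "t1", strand = "+", exons = rbind(c(1000, 1200),
                                                c(1800, 2000))),
    list(id = "t2", strand = "-", exons = cbind(1900, 2600))))
  cls <- data.frame(transcript_id = c("t1", "t2"),
                    class = c("lincRNA", "lincRNA"), nat_subtype = NA,
                    partner_gene = NA, stringsAsFactors = FALSE)
  loci <- merge_transcripts_to_loci(ts, cls)   # 2 loci (opposite strands)
  gt <- make_gt(matrix("AB", 3, 4), pos = c(1100L, 1500L, 1950L))
  rec <- snps_in_lncrna(gt, loci, ts)
  expect_equal(rec$context[rec$snp_id == "s001"], "exon")
  expect_equal(rec$context[rec$snp_id == "s002"], "intron")
  # position inside two overlapping loci annotates both
  expect_equal(sum(rec$snp_id == "s003"), 2L)
  expect_setequal(rec$context[rec$snp_id == "s003"], c("exon", "exon"))
})

test_that("kinship has VanRaden structure", {
  set.seed(131)
  calls <- matrix(sample(c("AA", "AB", "BB"), 50 * 6, TRUE,
                         prob = c(.45, .3, .25)), 50, 6)
  calls[, 6] <- calls[, 5]                    # duplicated individual
  gt <- make_gt(calls)
  K <- kinship_matrix(gt)
  expect_equal(K, t(K))
  expect_equal(K[5, 6], K[5, 5])
  expect_equal(K[6, ], K[5, ], ignore_attr = TRUE)
  # unrelated simulated individuals: off-diagonal mean near zero
  cfg <- sim_config(seed = 5, n_individuals = 40, n_snps = 5000,
                    n_subpops = 1, fst = 0, missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  K2 <- kinship_matrix(sim$gt)
  expect_lt(abs(mean(K2[upper.tri(K2)])), 0.05)
  expect_error(kinship_matrix(make_gt(matrix("AA", 2, 5))), "polymorphic")
})

test_that("REML reduces to ordinary least squares when K is identity", {
  set.seed(141)
  n <- 120
  y <- rnorm(n, sd = 2)
  vc <- reml_variance_components(y, NULL, diag(n))
  expect_equal(vc$sg2 + vc$se2, var(y), tolerance = 1e-6)
})

test_that("REML recovers planted heritability", {
  set.seed(151)
  n <- 300
  cfg <- sim_config(seed = 9, n_individuals = n, n_snps = 400,
                    missing_rate = 0, h2 = 0.5)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, sim$gt, sim$Q)
  vc <- reml_variance_components(ph$y, cbind(1, sim$Q[, -ncol(sim$Q)]),
                                 ph$K_true)
  expect_lt(abs(vc$h2 - 0.5), 0.2)   # single replicate; tight case in
                                     # the acceptance suite
})

test_that("scan with sigma_g = 0 equals ordinary regression", {
  set.seed(161)
  n <- 60
  calls <- matrix(sample(c("AA", "AB", "BB"), 20 * n, TRUE), 20, n)
  gt <- make_gt(calls)
  y <- rnorm(n)
  res <- mlm_scan(y, gt, Q = NULL, K = matrix(0, n, n))
  dos <- genotype_dosage(gt)
  for (k in sample(nrow(dos), 5)) {
    fit <- summary(lm(y ~ dos[k, ]))$coefficients
    want <- fit[2, 4]
    got <- res$p_value[res$snp_id == gt$snps$snp_id[k]]
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("consistent permutation of individuals leaves p-values fixed", {
  set.seed(171)
  cfg <- sim_config(seed = 13, n_individuals = 50, n_snps = 60,
                    missing_rate = 0)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, sim$gt, sim$Q)
  base <- mlm_scan(ph$y, sim$gt, Q = sim$Q, K = ph$K_true)
  perm <- sample(50)
  gt_p <- genotype_table(sim$gt$snps, sim$gt$calls[, perm])
  res_p <- mlm_scan(ph$y[perm], gt_p, Q = sim$Q[perm, ],
                    K = ph$K_true[perm, perm])
  expect_equal(res_p$p_value[match(base$snp_id, res_p$snp_id)],
               base$p_value, tolerance = 1e-8)
})

test_that("-log10 transform matches the printed convention", {
  expect_equal(round(-log10(5.01e-08), 1), 7.3)
  gt <- make_gt(matrix(rep(c("AA", "AB", "BB"), each = 10), 1, 30))
  y <- c(rnorm(10, 0), rnorm(10, 1), rnorm(10, 2))
  res <- mlm_scan(y, gt, K = diag(30))
  expect_equal(res$neglog10_p, -log10(res$p_value))
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("Q+K controls structure-driven inflation better than no model", {
  set.seed(181)
  cfg <- sim_config(seed = 17, n_individuals = 120, n_snps = 400,
                    n_subpops = 3, fst = 0.25, missing_rate = 0,
                    h2 = 0, q_effect = c(-1, 0, 1))
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(cfg, sim$gt, sim$Q)
  gtf <- filter_snps(sim$gt)
  res_qk <- mlm_scan(ph$y, gtf, Q = sim$Q, K = kinship_matrix(gtf))
  dos <- genotype_dosage(gtf)
  p_naive <- apply(dos, 1, function(x) {
    if (var(x) == 0) return(NA_real_)
    summary(lm(ph$y ~ x))$coefficients[2, 4]
  })
  chisq_qk <- qchisq(1 - res_qk$p_value, 1)
  chisq_nv <- qchisq(1 - p_naive[!is.na(p_naive)], 1)
  infl_qk <- median(chisq_qk) / qchisq(0.5, 1)
  infl_nv <- median(chisq_nv) / qchisq(0.5, 1)
  expect_lt(abs(infl_qk - 1), abs(infl_nv - 1))
})

test_that("monomorphic SNPs are skipped with a warning", {
  calls <- rbind(rep("AA", 30),
                 sample(c("AA", "AB", "BB"), 30, TRUE))
  gt <- make_gt(calls)
  expect_warning(res <- mlm_scan(rnorm(30), gt, K = diag(30)),
                 "monomorphic")
  expect_equal(nrow(res), 1L)
})
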