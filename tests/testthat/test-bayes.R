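test_that("eSNP identification keeps the boundary and collapses duplicates", {
  # the published GNGT2 eSNPs: both the genome-wide significant eQTL and the
  # boundary case at exactly the default threshold count as eSNPs
  eqtl <- data.frame(
    rsid = c("rs17637472", "rs1867087", "rs_weak", "rs17637472"),
    gene_id = c("GNGT2", "GNGT2", "GNGT2", "GNGT2"),
    pvalue = c(2.98e-8, 1.0e-4, 1.1e-4, 5e-8),
    stringsAsFactors = FALSE)
  es <- identify_esnps(eqtl, p_threshold = 1e-4)
  expect_setequal(es$rsid, c("rs17637472", "rs1867087"))
  expect_equal(es$p_eqtl[es$rsid == "rs17637472"], 2.98e-8)  # smallest p kept

  expect_equal(nrow(identify_esnps(eqtl[0, ], 1e-4)), 0)
  expect_error(identify_esnps(eqtl, 0), "p_threshold")
})

test_that("the log Bayes factor has its closed form, sign behaviour and
          monotonicity", {
  # direct evaluation at z = 0
  expect_equal(snp_log_bayes_factor(0, 0.1), 0.5 * log(1 / 1.1),
               tolerance = 1e-12)
  # a GWAS-significant eSNP (published p = 3.40e-8) scores positively
  z <- qnorm(3.40e-8 / 2, lower.tail = FALSE)
  expect_gt(snp_log_bayes_factor(z, 0.1), 0)
  # a null eSNP scores negatively
  expect_lt(snp_log_bayes_factor(0.5, 0.1), 0)
  # increasing in z^2
  expect_gt(snp_log_bayes_factor(2, 0.1), snp_log_bayes_factor(1, 0.1))
  expect_error(snp_log_bayes_factor(Inf, 0.1), "non-finite")
  expect_error(snp_log_bayes_factor(1, -1), "prior_w")
})

test_that("LD pruning is greedy by eQTL p and matches a brute-force check", {
  n <- 400
  set.seed(42)
  base <- rbinom(n, 2, 0.3)
  m <- cbind(s1 = base, s2 = base,                      # r^2 = 1 pair
             s3 = rbinom(n, 2, 0.3),
             s4 = rbinom(n, 2, 0.4),
             s5 = base + (rbinom(n, 1, 0.05)))          # high r^2 with s1
  m[m > 2] <- 2
  panel <- panel_from_matrix(m)

  # identical columns: only the smaller-p one survives
  es <- data.frame(rsid = c("s1", "s2"), gene_id = "G",
                   p_eqtl = c(1e-6, 1e-3), stringsAsFactors = FALSE)
  expect_equal(prune_esnps_by_ld(es, panel, 0.8)$rsid, "s1")

  # all r^2 = 0 (independent columns): everything kept
  es <- data.frame(rsid = c("s3", "s4"), gene_id = "G",
                   p_eqtl = c(0.01, 0.02), stringsAsFactors = FALSE)
  expect_equal(nrow(prune_esnps_by_ld(es, panel, 0.8)), 2)

  # 5-SNP fixture: greedy result equals an independent re-implementation
  es <- data.frame(rsid = paste0("s", 1:5), gene_id = "G",
                   p_eqtl = c(0.003, 0.001, 0.004, 0.002, 0.005),
                   stringsAsFactors = FALSE)
  got <- prune_esnps_by_ld(es, panel, 0.5)$rsid
  # oracle: explicit nested-loop greedy over the p-sorted order
  r2 <- cor(m)^2
  ord <- es$rsid[order(es$p_eqtl)]
  kept <- character(0)
  for (s in ord) {
    ok <- TRUE
    for (k in kept) if (r2[s, k] > 0.5) ok <- FALSE
    if (ok) kept <- c(kept, s)
  }
  expect_identical(got, kept)

  # SNPs absent from the panel are kept with a warning
  es <- data.frame(rsid = c("s1", "nopanel"), gene_id = "G",
                   p_eqtl = c(0.01, 0.02), stringsAsFactors = FALSE)
  expect_warning(out <- prune_esnps_by_ld(es, panel, 0.8), "absent")
  expect_true("nopanel" %in% out$rsid)
})

test_that("gene LBF aggregation is an exact order-invariant sum", {
  sc <- data.frame(gene_id = "G1", rsid = c("a", "b", "c"),
                   log_bf = c(1.2, -0.3, 0.5), stringsAsFactors = FALSE)
  expect_equal(gene_lbf("G1", sc)$lbf, 1.4, tolerance = 1e-12)
  expect_equal(gene_lbf("G1", sc[c(3, 1, 2), ])$lbf, 1.4, tolerance = 1e-12)
  expect_equal(gene_lbf("G1", sc[1, ])$lbf, 1.2)
  sc$gene_id[2] <- "G2"
  expect_error(gene_lbf("G1", sc), "G2")
})

test_that("run_bayes scores planted genes, omits eSNP-free genes, and
          reaches the simulated-p floor", {
  st <- small_study(seed = 1)
  res <- run_bayes(st$gwas, st$eqtl, st$panel, B = 200, seed = 1)

  # only genes with eSNPs appear; planted genes all score
  expect_true(all(st$truth$planted_genes %in% res$gene_id))
  contrib <- attr(res, "contributions")
  expect_setequal(res$gene_id, unique(contrib$gene_id))
  expect_true(all(res$n_esnps >= 1))

  # per-gene lbf equals the sum of its contributions exactly
  sums <- tapply(contrib$log_bf, contrib$gene_id, sum)
  expect_equal(as.numeric(sums[res$gene_id]), res$lbf, tolerance = 1e-12)

  # scenario labels partition scored eSNPs by the sign of log_bf
  expect_true(all((contrib$log_bf > 0) == (contrib$scenario == "positive")))

  # z_gwas reconstructs the two-sided p
  expect_equal(2 * pnorm(-contrib$z_gwas), contrib$p_gwas, tolerance = 1e-9)

  # nearly all planted genes are significant (weakly-drawn signals can slip);
  # every p respects the add-one bounds
  planted <- res[res$gene_id %in% st$truth$planted_genes, ]
  expect_gte(sum(planted$simulated_p < 0.05), 4)
  expect_true(all(res$simulated_p >= 1 / 201 & res$simulated_p <= 1))

  expect_error(run_bayes(st$gwas, st$eqtl, st$panel, B = 50), ">= 100")

  # input order of eQTL rows does not change the result
  shuffled <- st$eqtl[rev(seq_len(nrow(st$eqtl))), ]
  res2 <- run_bayes(st$gwas, shuffled, st$panel, B = 200, seed = 1)
  expect_equal(res2, res, tolerance = 1e-12)
})

test_that("simulated p is exactly 1 when no score can beat the observed tie", {
  # one gene whose single eSNP carries z = 0: every permutation gives an lbf
  # >= the observed one, so the ceiling p = 1 is exact
  gwas <- data.frame(rsid = sprintf("rs%02d", 1:20), chrom = "chr1",
                     pos = 1:20, ea = "A", oa = "G",
                     beta = c(0, rnorm(19)), se = 1, pvalue = NA, n = 100)
  gwas$pvalue <- 2 * pnorm(-abs(gwas$beta))
  results <- data.frame(gene_id = "G1",
                        lbf = snp_log_bayes_factor(0, 0.1), n_esnps = 1L)
  attr(results, "contributions") <- data.frame(
    gene_id = "G1", rsid = "rs01", stringsAsFactors = FALSE)
  out <- simulated_gene_pvalues(results, gwas, B = 100, seed = 9)
  expect_equal(out$simulated_p, 1)
})

test_that("simulated p reaches the 1/(B+1) floor when the observed score
          beats every null replicate", {
  # a single huge z in a large pool: the only way a null replicate ties the
  # observed score is to reassign that z to the same SNP, which the fixed
  # seed never does in 100 replicates
  n <- 5000
  gwas <- data.frame(rsid = sprintf("rs%04d", 1:n), chrom = "chr1",
                     pos = 1:n, ea = "A", oa = "G",
                     beta = c(10, rep(0, n - 1)), se = 1, pvalue = NA, n = 100)
  gwas$pvalue <- 2 * pnorm(-abs(gwas$beta))
  results <- data.frame(gene_id = "G1",
                        lbf = snp_log_bayes_factor(10, 0.1), n_esnps = 1L)
  attr(results, "contributions") <- data.frame(
    gene_id = "G1", rsid = "rs0001", stringsAsFactors = FALSE)
  out <- simulated_gene_pvalues(results, gwas, B = 100, seed = 9)
  expect_equal(out$simulated_p, 1 / 101)
})

test_that("BH adjustment matches hand-computed step-up examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  # p(i) * 4 / i = 0.04 for every i
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})
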