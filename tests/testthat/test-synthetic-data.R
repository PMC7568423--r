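test_that("make_truth validates config and resolves a reproducible truth", {
  expect_error(sim_config(n_planted = 30, n_genes = 20), "n_planted")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(n_genes = 0), "n_genes")

  # empty planted set is valid
  t0 <- make_truth(sim_config(n_genes = 10, n_planted = 0), seed = 3)
  expect_length(t0$planted_genes, 0)

  # planted genes are distinct members of the universe
  tr <- make_truth(sim_config(n_genes = 1000, n_planted = 20), seed = 7)
  expect_length(unique(tr$planted_genes), 20)
  expect_true(all(tr$planted_genes %in% tr$genes$gene_id))
  expect_true(all(tr$planted_snps$rsid %in% tr$snps$rsid))

  # same config + seed twice -> identical truth
  tr2 <- make_truth(sim_config(n_genes = 1000, n_planted = 20), seed = 7)
  expect_identical(tr, tr2)
})

test_that("LD panel reproduces the thresholded AR(1) correlation structure", {
  # independence limit: ld_decay = 0
  cfg0 <- sim_config(n_genes = 40, snps_per_gene = 5, n_planted = 0,
                     ld_decay = 0, n_samples_panel = 500)
  p0 <- simulate_ld_panel(make_truth(cfg0, seed = 11))
  cc <- cor(p0$dosage[, 1:50])
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)

  # strong LD: adjacent correlation matches the bivariate-normal
  # integration oracle after thresholding, and exceeds 0.5 on average
  cfg9 <- sim_config(n_genes = 20, snps_per_gene = 10, n_planted = 0,
                     ld_decay = 0.9, block_size = 10, n_samples_panel = 500)
  tr <- make_truth(cfg9, seed = 5)
  panel <- simulate_ld_panel(tr)
  j <- seq_len(ncol(panel$dosage) - 1)
  same_block <- tr$snps$block[j] == tr$snps$block[j + 1]
  emp <- vapply(j[same_block], function(a) {
    cor(panel$dosage[, a], panel$dosage[, a + 1])
  }, numeric(1))
  oracle <- vapply(j[same_block], function(a) {
    oracle_threshold_cor(0.9, tr$snps$maf[a], tr$snps$maf[a + 1])
  }, numeric(1))
  expect_gt(mean(emp), 0.5)
  expect_lt(abs(mean(emp) - mean(oracle)), 0.03)

  # determinism
  expect_identical(panel$dosage, simulate_ld_panel(tr)$dosage)
})

test_that("GWAS simulation is calibrated under the null and plants its mean", {
  # null: genomic inflation near 1 at 5000 SNPs
  cfg <- sim_config(n_genes = 1000, snps_per_gene = 5, n_planted = 0)
  tr <- make_truth(cfg, seed = 2)
  gw <- simulate_gwas(tr, simulate_ld_panel(tr))
  expect_equal(nrow(gw), 5000)
  expect_true(all(gw$pvalue > 0 & gw$pvalue <= 1))
  expect_gt(lambda_gc(gw$pvalue), 0.9)
  expect_lt(lambda_gc(gw$pvalue), 1.1)

  # planted SNPs: mean |z| within 3 SE of the configured noncentrality 6
  zs <- unlist(lapply(1:50, function(s) {
    tr <- make_truth(small_config(), seed = s)
    panel <- simulate_ld_panel(tr)
    gw <- simulate_gwas(tr, panel)
    abs(gw$beta[match(tr$planted_snps$rsid, gw$rsid)])
  }))
  expect_lt(abs(mean(zs) - 6), 3 / sqrt(length(zs)))
})

test_that("eQTL simulation: null genes uniform, planted genes extreme,
          labels share the skeleton", {
  # null pairs ~ Uniform(0,1) at 1e4 pairs
  cfg <- sim_config(n_genes = 2000, snps_per_gene = 5, n_planted = 0)
  tr <- make_truth(cfg, seed = 13)
  eq <- simulate_eqtl(tr, dataset_label = "nullset")
  expect_gt(stats::ks.test(eq$pvalue, "punif")$p.value, 0.01)

  # planted genes at noncentrality 8: min cis p < 1e-10
  for (s in 1:10) {
    tr <- make_truth(small_config(eqtl_ncp = 8), seed = s)
    eq <- simulate_eqtl(tr, dataset_label = "d")
    minp <- tapply(eq$pvalue, eq$gene_id, min)[tr$planted_genes]
    expect_true(all(minp < 1e-10))
  }

  # two labels: identical (snp, gene) keys, different p-values
  tr <- make_truth(small_config(), seed = 3)
  e1 <- simulate_eqtl(tr, dataset_label = "a")
  e2 <- simulate_eqtl(tr, dataset_label = "b")
  expect_identical(e1[c("rsid", "gene_id")], e2[c("rsid", "gene_id")])
  expect_false(any(e1$pvalue == e2$pvalue))

  # trans pairs are emitted and classified for configured genes
  cfgt <- small_config()
  trt <- make_truth(cfgt, seed = 3)
  cfgt$trans_genes <- trt$planted_genes[1]
  trt <- make_truth(cfgt, seed = 3)
  et <- simulate_eqtl(trt, dataset_label = "t")
  expect_equal(sum(et$cis_trans == "trans"), 1)
  reclass <- classify_cis_trans(et, trt$genes, trt$snps)
  expect_identical(reclass$cis_trans, et$cis_trans)
})

test_that("expression simulation: shape, null calibration, planted power", {
  cfg <- sim_config(n_genes = 2000, snps_per_gene = 1, n_planted = 0,
                    groups = c(SA = 44, notSA = 72, Control = 38))
  em <- simulate_expression(make_truth(cfg, seed = 21))
  expect_equal(dim(em$expr), c(2000, 154))
  expect_true(all(em$meta$group %in% c("SA", "notSA", "Control")))

  # null: ANOVA p fraction below 0.05 is 0.05 +/- 0.02
  deg <- deg_table(em)
  expect_lt(abs(mean(deg$anova_p < 0.05) - 0.05), 0.02)

  # planted shift of 3 noise-sd, groups of 20: power above the noncentral-F
  # oracle floor of 0.95
  cfg2 <- sim_config(n_genes = 300, snps_per_gene = 1, n_planted = 0,
                     n_deg = 100, deg_shift = 3,
                     groups = c(A = 20, B = 20, C = 20), deg_groups = "A")
  tr2 <- make_truth(cfg2, seed = 9)
  em2 <- simulate_expression(tr2)
  deg2 <- deg_table(em2)
  power <- mean(deg2$anova_p[deg2$gene_id %in% tr2$deg_genes] < 0.05)
  ncp <- 20 * ((3 - 1)^2 + 1 + 1)  # sum n_i (mu_i - mu_bar)^2 / sigma^2
  oracle_power <- stats::pf(stats::qf(0.95, 2, 57), 2, 57, ncp = ncp,
                            lower.tail = FALSE)
  expect_gt(oracle_power, 0.95)
  expect_gt(power, 0.95)

  expect_error(simulate_expression(tr2, groups = c(A = 1, B = 20)), ">= 2")
})
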