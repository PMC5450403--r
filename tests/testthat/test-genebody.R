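test_that("binomial site calls follow the non-conversion null", {
  ## 5C/0T at err 0.005: P = 0.005^5 ~ 3.1e-12 < 0.05 -> methylated
  expect_true(call_site_methylated(5, 0))
  expect_false(call_site_methylated(0, 5))
  ## 1C/19T: P(X>=1) = 1 - 0.995^20 ~ 0.095 > 0.05 -> unmethylated
  expect_false(call_site_methylated(1, 19))
  expect_equal(stats::pbinom(0, 20, 0.005, lower.tail = FALSE),
               1 - 0.995^20)
  expect_true(is.na(call_site_methylated(1, 1)))
  ## level threshold alternative
  expect_true(call_site_methylated(3, 2, method = "level:0.5"))
  expect_false(call_site_methylated(2, 3, method = "level:0.5"))
})

test_that("gene-body binomial classification follows the class rules", {
  ## build a panel where gene g1 has 10 fully methylated CG sites, g2 has
  ## 10 unmethylated CG sites, g3 is CHH-methylated (excluded)
  n <- 30L
  sites <- data.table::data.table(
    chrom = "c1", pos = seq_len(n) * 10L, strand = "+",
    context = rep(c("CG", "CG", "CHH"), each = 10L))
  cvec <- c(rep(18L, 10), rep(0L, 10), rep(18L, 10))
  tvec <- 20L - cvec
  panel <- panel_from_counts(sites, cvec, tvec, cvec, tvec)
  genes <- data.table::data.table(
    chrom = "c1", start = c(0L, 105L, 205L), end = c(101L, 205L, 301L),
    strand = "+", kind = "gene", id = c("g1", "g2", "g3"))
  bg <- c(CG = 0.2, CHG = 0.2, CHH = 0.2)
  cls <- classify_body_methylation(panel, genes, background_rates = bg)
  expect_equal(cls[gene_id == "g1", class], "methylated")
  ## P_CG for g1: P(X >= 10 | 10, 0.2) = 0.2^10
  expect_equal(cls[gene_id == "g1", P_CG], 0.2^10, tolerance = 1e-12)
  expect_equal(cls[gene_id == "g2", class], "unmethylated")
  expect_equal(cls[gene_id == "g2", P_CG], 1)
  expect_equal(cls[gene_id == "g3", class], "excluded")
})

test_that("low-coverage genes are excluded by the 40% rule", {
  sites <- data.table::data.table(
    chrom = "c1", pos = seq_len(10) * 5L, strand = "+", context = "CG")
  cvec <- c(rep(10L, 3), rep(0L, 7))
  tvec <- c(rep(0L, 3), rep(1L, 7))   # 7 of 10 sites below coverage 3
  panel <- panel_from_counts(sites, cvec, tvec, cvec, tvec)
  genes <- data.table::data.table(chrom = "c1", start = 0L, end = 60L,
                                  strand = "+", kind = "gene", id = "g")
  cls <- classify_body_methylation(panel, genes,
                                   background_rates = c(CG = 0.2, CHG = 0.2,
                                                        CHH = 0.2))
  expect_equal(cls$class, "excluded")
  expect_lt(cls$coverage_frac, 0.4)
})

test_that("simulated methylated/unmethylated gene sets classify without error", {
  cfg <- tiny_sim_cfg(n_cdmr = 0L, n_hdmc = 0L, n_hyper_genes = 0L,
                      n_hypo_genes = 0L, n_epi_shared = 0L,
                      n_epi_private = 0L, n_hybrid_dmrs = 0L,
                      n_lost_pairs = 0L)
  sim <- simulate_panel(cfg, seed = 21)
  genes <- sim_features(sim$genomes, "A")[kind == "gene"]
  cls <- classify_body_methylation(sim$panels$A, genes)
  truth <- sim$truth$gene_meta
  m <- merge(cls[, .(gene_id, class)], truth[, .(gene_id, bm)], by = "gene_id")
  ## no body-methylated truth gene called unmethylated, and vice versa
  expect_equal(nrow(m[bm == TRUE & class == "unmethylated"]), 0)
  expect_equal(nrow(m[bm == FALSE & class == "methylated"]), 0)
  ## both classes actually occur
  expect_true(any(m$class == "methylated"))
  expect_true(any(m$class == "unmethylated"))
})

test_that("DmCG rate is the exact body ratio", {
  genes <- data.table::data.table(chrom = "c1", start = 0L, end = 100L,
                                  strand = "+", kind = "gene", id = "g")
  cg <- data.table::data.table(chrom = "c1", pos = seq(0, 96, by = 4))
  dmc <- data.table::data.table(chrom = "c1", pos = c(4L, 8L, 12L, 16L, 20L))
  r <- dmcg_rate(genes, dmc, cg)
  expect_equal(r$dmcg_rate, 5 / 25)
  r0 <- dmcg_rate(genes, dmc[0], cg)
  expect_equal(r0$dmcg_rate, 0)
  rna <- dmcg_rate(genes, dmc, cg[0])
  expect_true(is.na(rna$dmcg_rate))
})

test_that("metaprofiles are flat for uniform methylation and strand-symmetric", {
  n <- 400L
  sites <- data.table::data.table(
    chrom = "c1", pos = seq_len(n) * 10L, strand = "+", context = "CG")
  panel <- panel_from_counts(sites, rep(5L, n), rep(5L, n), rep(5L, n),
                             rep(5L, n), "sp")
  feats <- data.table::data.table(chrom = "c1", start = c(1000L, 2500L),
                                  end = c(1800L, 3300L), strand = c("+", "-"))
  mp <- metaprofile(panel, feats, "CG", flank = 500L, body_bins = 10L,
                    flank_bins = 5L)
  expect_equal(nrow(mp), 20)
  expect_true(all(abs(mp$level - 0.5) < 1e-12, na.rm = TRUE))
  ## reversing all strands leaves a symmetric profile unchanged
  feats_flip <- data.table::copy(feats)[, strand := c("-", "+")]
  mp2 <- metaprofile(panel, feats_flip, "CG", flank = 500L, body_bins = 10L,
                     flank_bins = 5L)
  expect_equal(mp$level, mp2$level)
})

test_that("TE methylation contrast recovers a planted reduction", {
  set.seed(31)
  n_te <- 40L
  te_len <- 100L
  ## TEs 1..20 intragenic (low CHG), 21..40 intergenic (high CHG)
  tes <- data.table::data.table(
    chrom = "c1", start = (seq_len(n_te) - 1L) * 300L,
    end = (seq_len(n_te) - 1L) * 300L + te_len, strand = "+",
    kind = "TE_classI", id = paste0("te", seq_len(n_te)))
  genes <- data.table::data.table(chrom = "c1", start = 0L, end = 20L * 300L - 100L,
                                  strand = "+", kind = "gene", id = "g")
  sites <- data.table::rbindlist(lapply(seq_len(n_te), function(i) {
    data.table::data.table(chrom = "c1",
                           pos = tes$start[i] + seq(5L, 95L, by = 10L),
                           strand = "+", context = "CHG")
  }))
  p_true <- rep(c(0.3, 0.5), each = 10L * n_te / 2)
  cvec <- stats::rbinom(nrow(sites), 30, p_true)
  panel <- panel_from_counts(sites, cvec, 30L - cvec, cvec, 30L - cvec)
  res <- te_methylation_contrast(panel, tes, genes, "CHG")
  expect_lt(res$mean_intragenic, res$mean_intergenic)
  expect_lt(abs(res$difference + 0.2), 0.05)
  expect_lt(res$p, 0.001)
  ## no genes: every TE is intergenic, contrast undefined
  genes_none <- genes[0]
  expect_warning(res2 <- te_methylation_contrast(panel, tes, genes_none, "CHG"),
                 "empty")
  expect_true(is.na(res2$p))
})
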