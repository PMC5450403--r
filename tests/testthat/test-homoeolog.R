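## build a quartet map plus panels realizing specified window levels
quartet_fixture <- function(levels) {
  ## levels: data.table with win (0-based window index), pA, pD, pAs, pDs
  n_per <- 6L
  rows <- list()
  for (i in seq_len(nrow(levels))) {
    base <- levels$win[i] * 100L
    pos <- base + seq(5L, 95L, length.out = n_per)
    rows[[i]] <- data.table::data.table(
      site_id = 0L, context = "CG",
      chrom_A = "A01", pos_A = as.integer(pos), strand_A = "+",
      chrom_D = "D01", pos_D = as.integer(pos), strand_D = "+",
      chrom_As = "As01", pos_As = as.integer(pos), strand_As = "+",
      chrom_Ds = "Ds01", pos_Ds = as.integer(pos), strand_Ds = "+")
  }
  qmap <- data.table::rbindlist(rows)
  qmap[, site_id := .I]
  mk <- function(chrom, p_by_win) {
    sites <- data.table::data.table(
      chrom = chrom, pos = qmap$pos_A, strand = "+", context = "CG")
    p <- rep(p_by_win, each = n_per)
    cvec <- as.integer(round(30 * p))
    panel_from_counts(sites, cvec, 30L - cvec, cvec, 30L - cvec, chrom)
  }
  tet_sites <- data.table::data.table(
    chrom = c(rep("As01", nrow(qmap)), rep("Ds01", nrow(qmap))),
    pos = c(qmap$pos_As, qmap$pos_Ds), strand = "+", context = "CG")
  p_tet <- c(rep(levels$pAs, each = n_per), rep(levels$pDs, each = n_per))
  ctet <- as.integer(round(30 * p_tet))
  list(qmap = qmap,
       panel_a = mk("A01", levels$pA),
       panel_d = mk("D01", levels$pD),
       panel_tet = panel_from_counts(tet_sites, ctet, 30L - ctet, ctet,
                                     30L - ctet, "tet"))
}

test_that("cDMR/hDMC classification follows the threshold rules", {
  lv <- data.table::data.table(
    win = 0:3,
    pA  = c(0.9, 0.9, 0.9, 0.5),
    pD  = c(0.1, 0.1, 0.1, 0.4),
    pAs = c(0.9, 0.1, 0.6, 0.9),
    pDs = c(0.1, 0.9, 0.4, 0.1))
  fx <- quartet_fixture(lv)
  rec <- classify_cdmr_hdmc(fx$panel_a, fx$panel_d, fx$panel_tet, fx$qmap)
  rec <- rec[order(win_id)]
  ## window 3 fails the diploid gate (|0.5-0.4| < 0.6) and is absent
  expect_equal(nrow(rec), 3)
  expect_equal(rec[win_id == "As01:0", class], "cDMR")
  expect_equal(rec[win_id == "As01:100", class], "hDMC")
  expect_equal(rec[win_id == "As01:200", class], "neither")
  ## classes partition the gated records
  expect_true(all(rec$class %in% c("cDMR", "hDMC", "neither")))
})

test_that("DEG rule requires both 2-fold change and ANOVA significance", {
  ea <- rbind(g1 = c(100, 100), g2 = c(10, 12), g3 = c(40, 60))
  eb <- rbind(g1 = c(100, 100), g2 = c(100, 110), g3 = c(90, 110))
  degs <- call_degs(ea, eb)
  expect_false(degs[gene_id == "g1", deg])
  expect_true(degs[gene_id == "g2", deg])
  expect_gt(abs(degs[gene_id == "g2", log2_fc]), 1)
  expect_lt(degs[gene_id == "g2", p_value], 0.01)
  ## fold change exactly 2 fails the strict inequality (pseudocounted)
  expect_false(degs[gene_id == "g3", deg])
})

test_that("expression bias needs a 2-fold ratio shift with tight replicates", {
  mats <- list(
    A  = rbind(g1 = c(100, 102), g2 = c(100, 104), g3 = c(100, 101)),
    D  = rbind(g1 = c(50, 51), g2 = c(100, 99), g3 = c(100, 103)),
    As = rbind(g1 = c(100, 101), g2 = c(400, 410), g3 = c(100, 102)),
    Ds = rbind(g1 = c(50, 50), g2 = c(50, 52), g3 = c(100, 99)))
  bias <- expression_bias(mats)
  ## g1: A/D = As/Ds = 2 -> no bias; g2: 1 -> 8 -> bias; g3: flat
  expect_false(bias[pair_id == "g1", biased])
  expect_true(bias[pair_id == "g2", biased])
  expect_false(bias[pair_id == "g3", biased])
  expect_equal(bias[pair_id == "g2", shift], 3, tolerance = 0.1)
  ## missing value excludes the pair
  mats$As["g1", 1] <- NA
  bias2 <- expression_bias(mats)
  expect_true(is.na(bias2[pair_id == "g1", biased]))
})

test_that("methylation-shifted gene calls use conserved body levels", {
  lv <- data.table::data.table(
    win = 0:2,
    pA  = c(0.1, 0.9, 0.3),
    pD  = c(0.1, 0.1, 0.3),
    pAs = c(0.9, 0.2, 0.35),
    pDs = c(0.1, 0.1, 0.3))
  fx <- quartet_fixture(lv)
  genes <- data.table::data.table(
    chrom = "A01", start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
    strand = "+", kind = "gene", id = c("gHyper", "gHypo", "gFlat"))
  shifted <- call_methylation_shifted_genes(fx$panel_tet, fx$panel_a, genes,
                                            fx$qmap, "A")
  expect_equal(shifted[gene_id == "gHyper", class], "hyper")
  expect_equal(shifted[gene_id == "gHypo", class], "hypo")
  expect_equal(shifted[gene_id == "gFlat", class], "neither")
})

test_that("gene-loss contrast recovers the planted direction", {
  sim <- get_tiny_sim()
  pairs <- sim$truth$spikes$lost_pairs
  genes_a <- sim_features(sim$genomes, "A")[kind == "gene"]
  genes_d <- sim_features(sim$genomes, "D")[kind == "gene"]
  res <- gene_loss_contrast(pairs, sim$panels$A, sim$panels$D, genes_a,
                            genes_d)
  expect_gt(res$mean_lost, res$mean_retained)
  expect_lt(res$p, 0.05)
  ## swapping lost labels reverses the sign
  pairs_sw <- data.table::copy(pairs)[, lost := ifelse(lost == "A", "D", "A")]
  res_sw <- gene_loss_contrast(pairs_sw, sim$panels$A, sim$panels$D,
                               genes_a, genes_d)
  expect_equal(res_sw$mean_difference, -res$mean_difference, tolerance = 1e-9)
})

test_that("epiallele intersection reports shared windows and gene links", {
  mk_dmr <- function(wins, dir) data.table::data.table(
    win_id = paste0("As01:", wins), chrom = "As01", start = wins,
    end = wins + 100L, context = "CG", direction = dir)
  gh <- rbind(mk_dmr(c(0L, 100L, 200L), "hyper"), mk_dmr(400L, "hypo"))
  gb <- rbind(mk_dmr(c(100L, 200L), "hyper"), mk_dmr(c(400L, 500L), "hypo"))
  genes <- data.table::data.table(
    chrom = "As01", start = c(90L, 3000L), end = c(250L, 3400L),
    strand = "+", kind = "gene", id = c("g1", "gFar"))
  res <- identify_epialleles(gh, gb, genes, promoter_len = 0L)
  expect_equal(sum(res$summary$n_shared), 3)
  expect_setequal(unique(res$candidates$gene_id), "g1")
  ## disjoint sets yield nothing
  res0 <- identify_epialleles(mk_dmr(0L, "hyper"), mk_dmr(700L, "hyper"),
                              genes)
  expect_equal(nrow(res0$candidates), 0)
  ## identical sets: shared fraction 1
  res1 <- identify_epialleles(gh, gh, genes, promoter_len = 0L)
  expect_true(all(res1$summary$shared_fraction == 1))
  ## promoter association picks up a DMR 1 kb upstream of gFar
  gh_p <- mk_dmr(2200L, "hyper"); gb_p <- mk_dmr(2200L, "hyper")
  res_p <- identify_epialleles(gh_p, gb_p, genes, promoter_len = 2000L)
  expect_true("gFar" %in% res_p$candidates$gene_id)
  res_np <- identify_epialleles(gh_p, gb_p, genes, promoter_len = 0L)
  expect_false("gFar" %in% res_np$candidates$gene_id)
})
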