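## small helper: a panel with n sites at fixed counts
flat_sites <- function(n, context = "CG") {
  data.table::data.table(chrom = "c1", pos = seq_len(n) * 10L, strand = "+",
                         context = context)
}

test_that("DmC calling applies the delta and p thresholds", {
  s <- flat_sites(3)
  ## site 1: clear difference; site 2: delta 0.4 below cutoff; site 3: equal
  pa <- panel_from_counts(s, c(20L, 12L, 10L), c(0L, 8L, 10L),
                          c(20L, 12L, 10L), c(0L, 8L, 10L), "a")
  pb <- panel_from_counts(s, c(0L, 4L, 10L), c(20L, 16L, 10L),
                          c(0L, 4L, 10L), c(20L, 16L, 10L), "b")
  dmc <- call_dmcs(pa, pb)
  expect_equal(nrow(dmc), 1)
  expect_equal(dmc$pos, 10L)
  expect_equal(dmc$delta, 1)
  expect_equal(dmc$p_value, 0)  # zero within-group variance, unequal means
})

test_that("sites under coverage are skipped and counted, not errors", {
  s <- flat_sites(2)
  pa <- panel_from_counts(s, c(20L, 1L), c(0L, 1L), c(20L, 20L), c(0L, 0L), "a")
  pb <- panel_from_counts(s, c(0L, 0L), c(20L, 20L), c(0L, 0L), c(20L, 20L), "b")
  dmc <- call_dmcs(pa, pb)
  expect_equal(attr(dmc, "skipped"), 1L)
  expect_equal(nrow(dmc), 1)
})

test_that("DmC calls match a brute-force aov oracle on a simulated pair", {
  pair <- simulate_site_pair(n_windows = 150, sites_per_window = 4,
                             n_spiked = 20, seed = 3)
  dmc <- call_dmcs(pair$panel_a, pair$panel_b)
  ## brute force: per-site loop with stats::aov
  pa <- pair$panel_a; pb <- pair$panel_b
  hits <- character(0)
  for (i in seq_len(nrow(pa))) {
    la <- c(pa$c_r1[i] / (pa$c_r1[i] + pa$t_r1[i]),
            pa$c_r2[i] / (pa$c_r2[i] + pa$t_r2[i]))
    lb <- c(pb$c_r1[i] / (pb$c_r1[i] + pb$t_r1[i]),
            pb$c_r2[i] / (pb$c_r2[i] + pb$t_r2[i]))
    if (pa$c_r1[i] + pa$t_r1[i] < 3 || pa$c_r2[i] + pa$t_r2[i] < 3 ||
        pb$c_r1[i] + pb$t_r1[i] < 3 || pb$c_r2[i] + pb$t_r2[i] < 3) next
    if (abs(mean(la) - mean(lb)) < 0.5) next
    if (stats::sd(c(la, lb)) == 0) next
    p <- if (stats::sd(la) == 0 && stats::sd(lb) == 0) 0 else aov_p(la, lb)
    if (p < 0.01) hits <- c(hits, paste0(pa$chrom[i], ":", pa$pos[i]))
  }
  got <- paste0(dmc$chrom, ":", dmc$pos)
  expect_setequal(got, hits)
})

test_that("window eligibility follows the cytosine-count rules", {
  ## 3 CG sites in one window: ineligible
  s3 <- flat_sites(3)
  p3 <- panel_from_counts(s3, rep(5L, 3), rep(5L, 3), rep(5L, 3), rep(5L, 3))
  wl <- window_levels(p3, "CG")
  expect_false(any(wl$eligible))
  ## 4 CG sites each 5C/5T: eligible, level 0.5
  s4 <- flat_sites(4)
  p4 <- panel_from_counts(s4, rep(5L, 4), rep(5L, 4), rep(5L, 4), rep(5L, 4))
  wl <- window_levels(p4, "CG")
  expect_true(wl$eligible[1])
  expect_equal(wl$l1[1], 0.5)
  expect_equal(wl$l2[1], 0.5)
  ## 16 CHH sites with one at coverage 2: site excluded -> 15 -> ineligible
  s16 <- data.table::data.table(chrom = "c1", pos = 0:15 * 6L, strand = "+",
                                context = "CHH")
  c1 <- rep(5L, 16); t1 <- rep(5L, 16)
  c1[1] <- 1L; t1[1] <- 1L
  p16 <- panel_from_counts(s16, c1, t1, rep(5L, 16), rep(5L, 16))
  wl <- window_levels(p16, "CHH")
  expect_equal(wl$n_sites[1], 15L)
  expect_false(wl$eligible[1])
  expect_error(window_levels(p16, "CpG"), "unknown context")
})

test_that("pooled window level is coverage-weighted; site-mean flag is not", {
  s <- flat_sites(4)
  ## one deep unmethylated site against three shallow methylated ones
  p <- panel_from_counts(s, c(0L, 3L, 3L, 3L), c(30L, 0L, 0L, 0L),
                         c(0L, 3L, 3L, 3L), c(30L, 0L, 0L, 0L))
  pooled <- window_levels(p, "CG")
  sitem <- window_levels(p, "CG", site_mean = TRUE)
  expect_equal(pooled$l1[1], 9 / 39)
  expect_equal(sitem$l1[1], 0.75)
})

test_that("DMR calling applies context cutoffs and direction", {
  pair <- simulate_site_pair(n_windows = 60, sites_per_window = 5,
                             n_spiked = 10, seed = 9)
  dmrs <- call_dmrs(pair$panel_a, pair$panel_b, "CG")
  expect_setequal(dmrs$win_id, pair$truth$win_id)
  expect_true(all(dmrs$direction == "hyper"))  # spikes are hyper in A
  ## identical panels: zero DMRs
  none <- call_dmrs(pair$panel_a, pair$panel_a, "CG")
  expect_equal(nrow(none), 0)
  ## CHH cutoff 0.2 admits a delta ~0.3 window
  chh <- simulate_site_pair(n_windows = 40, sites_per_window = 16,
                            n_spiked = 8, p_high = 0.35, p_low = 0.05,
                            frac_meth = 0, context = "CHH", seed = 12)
  dm_chh <- call_dmrs(chh$panel_a, chh$panel_b, "CHH")
  expect_true(length(intersect(dm_chh$win_id, chh$truth$win_id)) >= 6)
  ## ... but those same windows fail the CG/CHG cutoff of 0.5
  dm_cg_cut <- call_dmrs(chh$panel_a, chh$panel_b, "CHH", delta_cutoff = 0.5)
  expect_equal(nrow(dm_cg_cut), 0)
})

test_that("raising cutoffs or lowering alpha never increases call counts", {
  pair <- simulate_site_pair(n_windows = 120, sites_per_window = 5,
                             n_spiked = 25, p_high = 0.7, p_low = 0.1, seed = 4)
  n_base <- nrow(call_dmrs(pair$panel_a, pair$panel_b, "CG"))
  n_tight_d <- nrow(call_dmrs(pair$panel_a, pair$panel_b, "CG",
                              delta_cutoff = 0.7))
  n_tight_a <- nrow(call_dmrs(pair$panel_a, pair$panel_b, "CG", alpha = 0.01))
  expect_true(n_tight_d <= n_base)
  expect_true(n_tight_a <= n_base)
  dmc_base <- nrow(call_dmcs(pair$panel_a, pair$panel_b))
  dmc_tight <- nrow(call_dmcs(pair$panel_a, pair$panel_b, delta = 0.7,
                              alpha = 0.001))
  expect_true(dmc_tight <= dmc_base)
})

test_that("maintenance flags require same sign and threshold magnitude", {
  ## hybrid hyper DMR at window 0; tetraploids with delta 0.5 (conserved),
  ## 0.2 (below threshold), -0.5 (wrong sign)
  wl_of <- function(l) data.table::data.table(
    win_id = "c1:0", chrom = "c1", start = 0L, n_sites = 6L, eligible = TRUE,
    l1 = l, l2 = l)
  hyb <- wl_of(0.9); par <- wl_of(0.1)
  dmr <- call_dmrs_windows(hyb, par, "CG")
  expect_equal(nrow(dmr), 1)
  tets <- list(t1 = wl_of(0.6), t2 = wl_of(0.3), t3 = wl_of(0.0))
  ## deltas vs parent 0.1: +0.5 conserved, +0.2 not, -0.1 not
  res <- assess_maintenance(dmr, hyb, par, tets, "CG")
  expect_equal(unlist(res$records[, .(cons_t1, cons_t2, cons_t3)]),
               c(cons_t1 = TRUE, cons_t2 = FALSE, cons_t3 = FALSE))
  expect_true(res$records$conserved_in_any)
  expect_false(res$records$conserved_in_all)
})

test_that("feature overlap fractions partition DMRs with gene precedence", {
  feats <- data.table::data.table(
    chrom = "c1", start = c(100L, 150L, 500L), end = c(300L, 250L, 600L),
    strand = "+", kind = c("gene", "TE_classI", "TE_classII"),
    id = c("g", "te1", "te2"))
  dmrs <- data.table::data.table(
    chrom = "c1", start = c(180L, 520L, 900L), end = c(280L, 620L, 1000L))
  fr <- feature_overlap_fractions(dmrs, feats)
  expect_equal(fr$fraction, c(1, 1, 1) / 3)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$n[fr$class == "gene"], 1L)    # midpoint in gene AND TE
  expect_equal(fr$n[fr$class == "TE"], 1L)
  expect_equal(fr$n[fr$class == "intergenic"], 1L)
})
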