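test_that("methylation evolution respects branch lengths and rates", {
  n <- 2000L
  root <- rep(c(TRUE, FALSE), n / 2)
  ctx <- rep("CG", n)
  rates <- list(CG = c(gain = 0.02, loss = 0.05))
  ## zero-length branches: all tips identical to the root
  tips0 <- evolve_methylation("(a:0,b:0);", root, ctx, rates, seed = 1)
  expect_identical(tips0$a, root)
  expect_identical(tips0$b, root)
  ## zero rates: no change regardless of depth
  tips_r0 <- evolve_methylation("(a:50,b:50);", root, ctx,
                                list(CG = c(gain = 0, loss = 0)), seed = 1)
  expect_identical(tips_r0$a, root)
  ## two equidistant leaves: expected divergence within binomial CI
  b <- 2
  tips <- evolve_methylation(sprintf("(a:%g,b:%g);", b, b), root, ctx, rates,
                             seed = 7)
  p_flip_m <- 1 - exp(-rates$CG[["loss"]] * b)
  p_flip_u <- 1 - exp(-rates$CG[["gain"]] * b)
  ## per-site divergence probability (both lineages independent)
  p_m <- 2 * p_flip_m * (1 - p_flip_m)
  p_u <- 2 * p_flip_u * (1 - p_flip_u)
  p_div <- mean(c(p_m, p_u))
  obs <- mean(tips$a != tips$b)
  se <- sqrt(p_div * (1 - p_div) / n)
  expect_lt(abs(obs - p_div), 4 * se + 1e-9)
  expect_error(evolve_methylation("(a:-1,b:1);", root, ctx, rates),
               "non-negative")
})

test_that("simulated genomes plant recoverable conserved regions", {
  sim <- get_tiny_sim()
  g <- sim$genomes
  blocks <- select_conserved_regions(g$blocks$A_D)
  ## exactly the planted tracts survive the filter (decoys dropped)
  expect_length(blocks, nrow(g$tracts))
  expect_true(all(vapply(blocks, function(b) b$src$end - b$src$start,
                         numeric(1)) >= 2000))
  ## ortholog map size equals the planted gene count
  expect_equal(nrow(g$gene_meta), nrow(g$genes))
  ## A and As subgenome sequence are identical copies
  expect_identical(unname(g$genome_A[["A01"]]),
                   unname(g$genome_tet[["As01"]]))
})

test_that("the simulator is deterministic under a fixed seed", {
  cfg <- tiny_sim_cfg()
  s1 <- simulate_panel(cfg, seed = 33)
  s2 <- simulate_panel(cfg, seed = 33)
  expect_identical(s1$genomes$genome_A, s2$genomes$genome_A)
  expect_equal(s1$panels$wGh, s2$panels$wGh)
  expect_equal(s1$expression, s2$expression)
  expect_equal(s1$truth$spikes$hybrid_dmrs, s2$truth$spikes$hybrid_dmrs)
})

test_that("read sampling converges to the true probability at high depth", {
  sites <- data.table::data.table(chrom = "c", pos = 1:1000 * 3L,
                                  strand = "+", context = "CG")
  p <- rep(0.5, 1000)
  panel <- sample_read_counts(sites, p, "sp", depth = 1000, error_rate = 0,
                              seed = 5)
  lev <- panel$c_r1 / (panel$c_r1 + panel$t_r1)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(lev) - 0.5), 3 * se / sqrt(10))
  ## p = 1 with no error: every read methylated
  panel1 <- sample_read_counts(sites, rep(1, 1000), "sp", depth = 10,
                               error_rate = 0, seed = 6)
  expect_true(all(panel1$t_r1 == 0))
  ## depth 0: no coverage anywhere
  panel0 <- sample_read_counts(sites, p, "sp", depth = 0, seed = 7)
  expect_true(all(panel0$c_r1 + panel0$t_r1 == 0))
  expect_error(sample_read_counts(sites, rep(1.5, 1000), "sp", 10), "0,1")
})

test_that("hybrid construction reduces CHH and keeps parental CG alleles", {
  cfg <- tiny_sim_cfg()
  sim <- simulate_panel(cfg, seed = 41)
  nA <- nrow(sim$genomes$sites_A)
  ctx_a <- sim$genomes$sites_A$context
  hyb_a <- sim$meth$prob$A2D5[seq_len(nA)]
  par_a <- sim$meth$prob$A
  ## CG/CHG alleles equal the parent everywhere except spiked windows
  spiked <- sim$truth$spikes
  cg_rows <- which(ctx_a != "CHH")
  frac_same <- mean(hyb_a[cg_rows] == par_a[cg_rows])
  expect_gt(frac_same, 0.98)
  ## CHH alleles are the parent's probability times the reduction factor
  chh <- which(ctx_a == "CHH")
  expect_equal(hyb_a[chh], par_a[chh] * cfg$chh_reduction, tolerance = 1e-12)
})

test_that("maintenance truth flags follow the configured probability", {
  cfg <- tiny_sim_cfg(n_hybrid_dmrs = 60L, maintenance_prob = 1)
  sim <- simulate_panel(cfg, seed = 51)
  flags <- sim$truth$spikes$hybrid_dmrs
  wild_cols <- c("wGh", "wGb", "Gt", "Gm", "Gd")
  expect_true(all(as.matrix(flags[, wild_cols, with = FALSE])))
  cfg0 <- tiny_sim_cfg(n_hybrid_dmrs = 60L, maintenance_prob = 0)
  sim0 <- simulate_panel(cfg0, seed = 52)
  flags0 <- sim0$truth$spikes$hybrid_dmrs
  expect_false(any(as.matrix(flags0[, wild_cols, with = FALSE])))
  ## intermediate probability: mean within 4 binomial SEs
  cfg8 <- tiny_sim_cfg(n_hybrid_dmrs = 60L, maintenance_prob = 0.8)
  sim8 <- simulate_panel(cfg8, seed = 53)
  m <- mean(as.matrix(sim8$truth$spikes$hybrid_dmrs[, wild_cols, with = FALSE]))
  se <- sqrt(0.8 * 0.2 / (60 * 5))
  expect_lt(abs(m - 0.8), 4 * se)
  expect_error(sim_config(maintenance_prob = 1.2), "maintenance")
})

test_that("panel files written to disk reproduce the in-memory panels", {
  sim <- get_tiny_sim()
  dir <- withr::local_tempdir()
  write_sim <- getFromNamespace("write_sim", "polymeth")
  write_sim(sim, dir)
  back <- read_panel_dir(dir, species = "Gt")
  orig <- sim$panels$Gt
  expect_equal(nrow(back$Gt), nrow(orig))
  expect_equal(back$Gt$c_r1, orig$c_r1)
  expect_equal(back$Gt$g_r2, orig$g_r2)
  ## truth tables round-trip
  tm <- read_site_map(file.path(dir, "truth", "site_map.tsv"))
  expect_equal(nrow(tm), nrow(sim$truth$site_map))
})
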