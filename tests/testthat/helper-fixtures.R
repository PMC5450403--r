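## shared fixtures, built once per test run

## a small panel built directly from counts: one replicate table per entry
make_panel <- function(counts, species = "sp") {
  methylome_panel(counts, species)
}

## a two-replicate panel from site table + per-replicate c/t vectors
panel_from_counts <- function(sites, c1, t1, c2, t2, species = "sp") {
  r1 <- data.table::as.data.table(sites)[, `:=`(c = c1, t = t1)]
  r2 <- data.table::as.data.table(sites)[, `:=`(c = c2, t = t2)]
  methylome_panel(list(r1 = r1, r2 = r2), species)
}

## a tiny spiked simulation shared across test files (cached)
.fixture_env <- new.env(parent = emptyenv())

tiny_sim_cfg <- function(...) {
  sim_config(n_chromosomes = 1L, chrom_length = 150000L,
             n_hybrid_dmrs = 10L, n_cdmr = 6L, n_hdmc = 4L,
             n_epi_shared = 3L, n_epi_private = 5L, n_hyper_genes = 3L,
             n_hypo_genes = 2L, n_lost_pairs = 8L, ...)
}

get_tiny_sim <- function() {
  if (is.null(.fixture_env$tiny_sim)) {
    .fixture_env$tiny_sim <- simulate_panel(tiny_sim_cfg(), seed = 11)
  }
  .fixture_env$tiny_sim
}

## independent one-way ANOVA p via stats::aov (oracle)
aov_p <- function(a, b) {
  d <- data.frame(y = c(a, b), g = factor(rep(c("a", "b"), c(length(a), length(b)))))
  summary(stats::aov(y ~ g, data = d))[[1]][["Pr(>F)"]][1]
}
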