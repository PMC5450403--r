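#' Configuration for the synthetic methylome panel simulator
#'
#' Defines the simulated study panel: two diploid progenitors (A, D), their
#' interspecific F1 hybrid (A2D5), five wild allotetraploids (wGh, wGb, Gt,
#' Gm, Gd) and two cultivated forms (cGh, cGb), each with two bisulfite
#' replicates.  Genomes are built from conserved tracts (>= 2 kb, identical
#' between A and D and copied into the As/Ds subgenomes of the tetraploid
#' reference) interleaved with diverged tracts.  Methylation evolves as a
#' two-state per-site gain/loss process along the species tree; partial
#' levels arise only from read sampling.  Ground-truth features (hybrid
#' DMRs with a maintenance probability, cDMR/hDMC windows, wild-vs-
#' cultivated epiallele DMRs, methylation-shifted genes, gene-loss pairs)
#' are spiked with known coordinates and effect sizes.
#'
#' @param ... named overrides of any default.
#' @return list of class `polymeth_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chromosomes      = 2L,
    chrom_length       = 700000L,
    gc_content         = 0.34,
    conserved_tract_len = c(2000L, 3000L),
    diverged_tract_len = c(800L, 1500L),
    gene_len           = 1500L,
    te_len             = 400L,
    n_te_per_chrom     = 60L,
    spike_min_sites    = 6L,
    te_genic_frac      = c(A = 0.2, D = 0.4),
    ## species tree: diploid branches from the A/D ancestor; tetraploid stem
    ## (shared polyploid history) then the radiation with nested
    ## domestication; branch lengths in epimutation time units
    diploid_branch     = 3,
    tet_stem           = 0.5,
    tet_tree           = paste0(
      "(((wGh:0.3,cGh:0.3):0.4,Gt:0.7):0.5,",
      "(((wGb:0.3,cGb:0.3):0.4,Gd:0.7):0.3,Gm:1.0):0.2);"),
    ## per-context two-state gain/loss rates (per site per time unit)
    rates = list(CG = c(gain = 0.001, loss = 0.040),
                 CHG = c(gain = 0.010, loss = 0.040),
                 CHH = c(gain = 0.020, loss = 0.080)),
    ## root probabilities that a site starts methylated, by genomic class
    root_prob = list(
      CG  = c(bg = 0.25, te = 0.90, te_genic = 0.90, gene_bm = 0.85, gene_um = 0.02),
      CHG = c(bg = 0.08, te = 0.85, te_genic = 0.45, gene_bm = 0.05, gene_um = 0.05),
      CHH = c(bg = 0.05, te = 0.50, te_genic = 0.40, gene_bm = 0.03, gene_um = 0.03)),
    bm_gene_frac       = 0.6,
    ## true methylation level of a methylated / unmethylated site
    ## (cell-mixture ceiling)
    level_methylated   = c(CG = 0.90, CHG = 0.80, CHH = 0.45),
    level_unmethylated = c(CG = 0.01, CHG = 0.01, CHH = 0.01),
    chh_reduction      = 0.8,   # hybrid CHH probability multiplier
    ## spiked features
    n_hybrid_dmrs      = 200L,
    maintenance_prob   = 0.8,
    n_cdmr             = 200L,
    n_hdmc             = 50L,
    n_epi_shared       = 30L,
    n_epi_private      = 170L,
    n_hyper_genes      = 50L,
    n_hypo_genes       = 20L,
    n_lost_pairs       = 40L,
    ## read sampling
    depth              = 20,
    replicates         = 2L,
    error_rate         = 0.005,
    ## coding sequences / Ks
    cds_codons         = 100L,
    ks_rate            = 0.03,
    ks_shape           = 3,
    ## expression
    expr_coupling      = 0.5,
    expr_noise_sd      = 0.25,
    bias_log2          = 3,
    bias_prob_hdmc     = 0.85,
    bias_prob_background = 0.05,
    seed               = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  assert_that(length(unknown) == 0,
              "unknown simulator field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  assert_that(cfg$maintenance_prob >= 0 && cfg$maintenance_prob <= 1,
              "maintenance probability must be in [0,1]")
  assert_that(cfg$chh_reduction >= 0 && cfg$chh_reduction <= 1,
              "chh_reduction must be in [0,1]")
  assert_that(cfg$depth >= 0, "sequencing depth must be non-negative")
  for (ctx in names(cfg$rates)) {
    assert_that(all(cfg$rates[[ctx]] >= 0), "rates must be non-negative")
  }
  structure(cfg, class = c("polymeth_sim_config", "list"))
}

SIM_SPECIES <- c("A", "D", "A2D5", "wGh", "wGb", "Gt", "Gm", "Gd", "cGh", "cGb")
SIM_TETRAPLOIDS <- c("wGh", "wGb", "Gt", "Gm", "Gd", "cGh", "cGb")
SIM_WILD_TETRAPLOIDS <- c("wGh", "wGb", "Gt", "Gm", "Gd")

## the full 9-tip species tree implied by the config (hybrid excluded)
sim_true_tree <- function(cfg) {
  tet <- sub(";$", "", cfg$tet_tree)
  sprintf("(A:%g,D:%g,%s:%g);", cfg$diploid_branch, cfg$diploid_branch,
          tet, cfg$tet_stem)
}
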