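#' Sample bisulfite read counts from true methylation probabilities
#'
#' Per site and replicate, coverage ~ Poisson(depth); methylated reads
#' ~ Binomial(coverage, p(1-err) + (1-p)err); guanine-confirmation reads on
#' the complementary strand are an independent Poisson(depth) draw.
#'
#' @param sites site table (chrom, pos, strand, context).
#' @param prob true methylation probability per site (same order).
#' @param species species id for the panel.
#' @param depth mean sequencing depth.
#' @param replicates number of replicates (default 2).
#' @param error_rate bisulfite non-conversion / sequencing error rate.
#' @param seed RNG seed (optional).
#' @return a [methylome_panel()].
#' @export
sample_read_counts <- function(sites, prob, species, depth, replicates = 2L,
                               error_rate = 0.005, seed = NULL) {
  assert_that(all(prob >= 0 & prob <= 1), "probabilities must be in [0,1]")
  assert_that(depth >= 0, "depth must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sites)
  p_obs <- prob * (1 - error_rate) + (1 - prob) * error_rate
  reps <- lapply(seq_len(replicates), function(r) {
    cov <- stats::rpois(n, depth)
    cc <- stats::rbinom(n, cov, p_obs)
    dt <- data.table::data.table(
      chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
      context = sites$context, c = cc, t = cov - cc,
      g = stats::rpois(n, depth))
    dt
  })
  names(reps) <- paste0("r", seq_len(replicates))
  methylome_panel(reps, species)
}

#' Simulate a two-species site panel with optional spiked DMR windows
#'
#' A lightweight benchmark generator: `n_windows` consecutive 100-bp
#' windows, each carrying `sites_per_window` cytosines of one context on a
#' single chromosome.  Both species share the same per-site true
#' methylation probability (a two-state mixture) except in spiked windows,
#' where species A sites are set to `p_high` and species B sites to `p_low`
#' (true delta = p_high - p_low).  Read counts are sampled exactly as in
#' the full simulator.
#'
#' @param n_windows number of 100-bp windows (default 1000).
#' @param sites_per_window cytosines per window (default 8).
#' @param depth Poisson mean coverage (default 20).
#' @param n_spiked number of spiked (hyper-in-A) windows.
#' @param p_high,p_low spiked probabilities (default 0.85 / 0.05).
#' @param frac_meth mixture weight of the methylated state (default 0.3).
#' @param p_meth,p_unmeth probabilities of the two base states.
#' @param context site context label (default "CG").
#' @param error_rate non-conversion rate (default 0.005).
#' @param seed RNG seed.
#' @return list with `panel_a`, `panel_b`, `sites`, `truth` (spiked
#'   win_ids with the true delta).
#' @export
simulate_site_pair <- function(n_windows = 1000L, sites_per_window = 8L,
                               depth = 20, n_spiked = 0L, p_high = 0.85,
                               p_low = 0.05, frac_meth = 0.3, p_meth = 0.8,
                               p_unmeth = 0.05, context = "CG",
                               error_rate = 0.005, seed = 1L) {
  set.seed(seed)
  offs <- round(seq(5, 95, length.out = sites_per_window))
  pos <- as.integer(rep((seq_len(n_windows) - 1L) * 100L, each = sites_per_window) +
                      offs)
  sites <- data.table::data.table(chrom = "chr1", pos = pos, strand = "+",
                                  context = context)
  p <- ifelse(stats::runif(nrow(sites)) < frac_meth, p_meth, p_unmeth)
  p_a <- p; p_b <- p
  spiked <- integer(0)
  if (n_spiked > 0) {
    spiked <- sort(sample.int(n_windows, n_spiked))
    in_spike <- ((pos %/% 100L) + 1L) %in% spiked
    p_a[in_spike] <- p_high
    p_b[in_spike] <- p_low
  }
  panel_a <- sample_read_counts(sites, p_a, "spA", depth,
                                error_rate = error_rate,
                                seed = child_seed(seed, 101))
  panel_b <- sample_read_counts(sites, p_b, "spB", depth,
                                error_rate = error_rate,
                                seed = child_seed(seed, 102))
  truth <- data.table::data.table(
    win_id = paste0("chr1:", (spiked - 1L) * 100L),
    delta = p_high - p_low)
  list(panel_a = panel_a, panel_b = panel_b, sites = sites, truth = truth,
       prob_a = p_a, prob_b = p_b)
}

#' Simulate expression with methylation coupling and planted homoeolog bias
#'
#' Per ortholog gene and genome copy (A, D, As, Ds of each tetraploid),
#' log2 expression = baseline - coupling * (true body CG level - 0.2), plus
#' a planted log2 homoeolog-bias shift on the tetraploid As copy: hDMC
#' genes receive the shift with probability `bias_prob_hdmc` in the
#' direction implied by their methylation change (hypomethylated subgenome
#' up), other spiked genes with the background probability.  Replicate RPKM
#' values add lognormal noise; counts are Poisson with mean 10 x RPKM.
#'
#' @param genomes a [simulate_genomes()] object.
#' @param meth a [simulate_methylomes()] object.
#' @param seed RNG seed.
#' @return list with `expression` (long table: species, gene_id, copy,
#'   rpkm_r1, rpkm_r2, count_r1, count_r2) and `truth` (per gene: class,
#'   planted bias flag and sign, baseline).
#' @export
simulate_expression <- function(genomes, meth, seed = genomes$cfg$seed + 2L) {
  cfg <- genomes$cfg
  set.seed(seed)
  sA <- genomes$sites_A; sD <- genomes$sites_D
  genes <- genomes$gene_meta$gene_id
  ia <- which(!is.na(sA$gene_id) & sA$context == "CG")
  idd <- which(!is.na(sD$gene_id) & sD$context == "CG")
  body_idx_A <- split(ia, sA$gene_id[ia])[genes]
  body_idx_D <- split(idd, sD$gene_id[idd])[genes]
  names(body_idx_A) <- names(body_idx_D) <- genes
  body_level <- function(p, idx) if (length(idx)) mean(p[idx]) else 0.1
  nA <- nrow(sA)
  baseline <- stats::setNames(stats::rnorm(length(genes), 5, 1), genes)

  ## planted bias
  ch <- meth$spikes$cdmr_hdmc %||%
    data.table::data.table(gene_id = character(), class = character(),
                           direction = character())
  cls <- stats::setNames(rep("none", length(genes)), genes)
  cls[ch$gene_id] <- ch$class
  a_high <- stats::setNames(rep(NA, length(genes)), genes)
  a_high[ch$gene_id] <- ch$direction == "A_high"
  bias_sign <- stats::setNames(rep(0, length(genes)), genes)
  planted <- stats::setNames(rep(FALSE, length(genes)), genes)
  for (g in genes) {
    if (cls[[g]] == "hDMC") {
      if (stats::runif(1) < cfg$bias_prob_hdmc) {
        planted[[g]] <- TRUE
        ## hDMC flips the diploid difference: A_high diploid -> As copy is
        ## hypomethylated? no: hDMC means As/Ds reversed, so A_high gives
        ## As low methylation -> As expressed higher
        bias_sign[[g]] <- if (isTRUE(a_high[[g]])) 1 else -1
      }
    } else if (cls[[g]] == "cDMR") {
      if (stats::runif(1) < cfg$bias_prob_background) {
        planted[[g]] <- TRUE
        bias_sign[[g]] <- sample(c(-1, 1), 1)
      }
    }
  }

  species_list <- c("A", "D", SIM_TETRAPLOIDS)
  rows <- list()
  for (sp in species_list) {
    copies <- if (sp %in% c("A", "D")) sp else c("As", "Ds")
    for (cp in copies) {
      lv <- vapply(genes, function(g) {
        switch(cp,
          A = body_level(meth$prob$A, body_idx_A[[g]]),
          D = body_level(meth$prob$D, body_idx_D[[g]]),
          As = body_level(meth$prob[[sp]][seq_len(nA)], body_idx_A[[g]]),
          Ds = body_level(meth$prob[[sp]][-seq_len(nA)], body_idx_D[[g]]))
      }, numeric(1))
      shift <- if (cp == "As") bias_sign[genes] * cfg$bias_log2 else 0
      mu <- baseline[genes] - cfg$expr_coupling * (lv - 0.2) + shift
      rpkm <- sapply(1:2, function(r) {
        2^(mu + stats::rnorm(length(genes), 0, cfg$expr_noise_sd))
      })
      counts <- matrix(stats::rpois(length(rpkm), 10 * rpkm), ncol = 2)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        species = sp, gene_id = genes, copy = cp,
        rpkm_r1 = rpkm[, 1], rpkm_r2 = rpkm[, 2],
        count_r1 = counts[, 1], count_r2 = counts[, 2])
    }
  }
  truth <- data.table::data.table(
    gene_id = genes, class = cls[genes], planted_bias = planted[genes],
    bias_sign = bias_sign[genes], baseline = baseline[genes])
  list(expression = data.table::rbindlist(rows), truth = truth)
}
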