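#' Simulate the full species methylome panel
#'
#' End-to-end generator: genomes and annotations, methylation evolution
#' with spiked ground-truth features, bisulfite read sampling for all ten
#' species (A, D, A2D5 hybrid, five wild and two cultivated
#' allotetraploids; two replicates each), and coupled expression.  With
#' `out_dir`, every input the analysis pipeline reads is written to disk
#' (FASTA genomes, GFF3 annotations, MAF-like alignment blocks, CX-style
#' methylome reports, expression tables, coding sequences) together with
#' `truth/` tables describing the planted features.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed; child seeds are derived per stage.
#' @param out_dir optional output directory.
#' @param write_probabilities also write per-site true probabilities
#'   (large; default FALSE).
#' @param spike plant ground-truth features (default TRUE).
#' @return list (class `polymeth_sim`) with `cfg`, `genomes`, `meth`,
#'   `panels` (named list of [methylome_panel()]), `expression`, `truth`.
#' @export
simulate_panel <- function(cfg = sim_config(), seed = cfg$seed,
                           out_dir = NULL, write_probabilities = FALSE,
                           spike = TRUE) {
  genomes <- simulate_genomes(cfg, child_seed(seed, 1))
  meth <- simulate_methylomes(genomes, child_seed(seed, 2), spike = spike)
  expr <- simulate_expression(genomes, meth, child_seed(seed, 3))
  panels <- sim_sample_panels(genomes, meth, seed)
  truth <- list(
    tree = sim_true_tree(cfg),
    site_map = genomes$truth_map,
    spikes = meth$spikes,
    expr_truth = expr$truth,
    gene_meta = genomes$gene_meta)
  sim <- structure(list(cfg = cfg, seed = seed, genomes = genomes,
                        meth = meth, panels = panels,
                        expression = expr$expression, truth = truth),
                   class = "polymeth_sim")
  if (!is.null(out_dir)) {
    write_sim(sim, out_dir, write_probabilities)
  }
  sim
}

## site tables per species coordinate system
sim_site_tables <- function(genomes) {
  key <- c("chrom", "pos", "strand", "context")
  sA <- genomes$sites_A[, key, with = FALSE]
  sD <- genomes$sites_D[, key, with = FALSE]
  s_tet <- data.table::rbindlist(list(
    data.table::copy(sA)[, chrom := sub("^A", "As", chrom)],
    data.table::copy(sD)[, chrom := sub("^D", "Ds", chrom)]))
  s_hyb <- data.table::rbindlist(list(sA, sD))
  list(A = sA, D = sD, AD = s_hyb, tet = s_tet)
}

sim_sample_panels <- function(genomes, meth, seed) {
  cfg <- genomes$cfg
  st <- sim_site_tables(genomes)
  panels <- list()
  sp_sites <- c(A = "A", D = "D", A2D5 = "AD",
                stats::setNames(rep("tet", length(SIM_TETRAPLOIDS)),
                                SIM_TETRAPLOIDS))
  for (i in seq_along(sp_sites)) {
    sp <- names(sp_sites)[i]
    panels[[sp]] <- sample_read_counts(
      st[[sp_sites[[i]]]], meth$prob[[sp]], sp, cfg$depth, cfg$replicates,
      cfg$error_rate, seed = child_seed(seed, 10L + i))
  }
  panels
}

#' Feature tables (genes and TEs) of a simulated genome
#'
#' @param genomes a [simulate_genomes()] object.
#' @param which coordinate system: diploid "A", diploid "D", or the
#'   allotetraploid reference "tet" (As+Ds chromosomes, gene ids suffixed
#'   by subgenome).
#' @return data.table with chrom, start, end, strand, kind, id.
#' @export
sim_features <- function(genomes, which = c("A", "D", "tet")) {
  which <- match.arg(which)
  g <- genomes$genes
  if (which == "A") {
    genes <- g[, .(chrom = chrom_A, start = gstart_A, end = gend_A, strand,
                   kind = "gene", id = gene_id)]
    tes <- genomes$tes_A[, .(chrom, start, end, strand, kind, id)]
  } else if (which == "D") {
    genes <- g[, .(chrom = chrom_D, start = gstart_D, end = gend_D, strand,
                   kind = "gene", id = gene_id)]
    tes <- genomes$tes_D[, .(chrom, start, end, strand, kind, id)]
  } else {
    genes <- data.table::rbindlist(list(
      g[, .(chrom = chrom_As, start = gstart_A, end = gend_A, strand,
            kind = "gene", id = paste0(gene_id, "_As"))],
      g[, .(chrom = chrom_Ds, start = gstart_D, end = gend_D, strand,
            kind = "gene", id = paste0(gene_id, "_Ds"))]))
    tes <- data.table::rbindlist(list(
      data.table::copy(genomes$tes_A)[, chrom := sub("^A", "As", chrom)],
      data.table::copy(genomes$tes_D)[, chrom := sub("^D", "Ds", chrom)]))[
      , .(chrom, start, end, strand, kind, id)]
  }
  data.table::rbindlist(list(genes, tes))
}

write_sim <- function(sim, out_dir, write_probabilities = FALSE) {
  dirs <- file.path(out_dir, c("genomes", "annotations", "alignments",
                               "methylomes", "expression", "truth"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  g <- sim$genomes
  write_genome_fasta(g$genome_A, file.path(out_dir, "genomes", "A.fa"))
  write_genome_fasta(g$genome_D, file.path(out_dir, "genomes", "D.fa"))
  write_genome_fasta(g$genome_tet, file.path(out_dir, "genomes", "tet.fa"))
  for (w in c("A", "D", "tet")) {
    write_features(sim_features(g, w),
                   file.path(out_dir, "annotations",
                             paste0("features_", w, ".gff3")))
  }
  write_alignment_blocks(g$blocks$A_tet,
                         file.path(out_dir, "alignments", "A_tet.maf"))
  write_alignment_blocks(g$blocks$D_tet,
                         file.path(out_dir, "alignments", "D_tet.maf"))
  write_alignment_blocks(g$blocks$A_D,
                         file.path(out_dir, "alignments", "A_D.maf"))
  for (sp in names(sim$panels)) {
    write_panel_cx(sim$panels[[sp]],
                   file.path(out_dir, "methylomes"), sp)
  }
  data.table::fwrite(sim$expression,
                     file.path(out_dir, "expression", "expression.tsv"),
                     sep = "\t")
  write_genome_fasta(g$cds, file.path(out_dir, "cds.fa"))
  tr <- sim$truth
  writeLines(tr$tree, file.path(out_dir, "truth", "tree.nwk"))
  write_site_map(tr$site_map, file.path(out_dir, "truth", "site_map.tsv"))
  for (nm in names(tr$spikes)) {
    data.table::fwrite(tr$spikes[[nm]],
                       file.path(out_dir, "truth", paste0(nm, ".tsv")),
                       sep = "\t")
  }
  data.table::fwrite(tr$expr_truth,
                     file.path(out_dir, "truth", "expression_truth.tsv"),
                     sep = "\t")
  data.table::fwrite(tr$gene_meta,
                     file.path(out_dir, "truth", "gene_meta.tsv"), sep = "\t")
  if (write_probabilities) {
    st <- sim_site_tables(g)
    for (sp in names(sim$meth$prob)) {
      tab <- st[[if (sp %in% c("A", "D")) sp else if (sp == "A2D5") "AD" else "tet"]]
      out <- data.table::copy(tab)[, prob := sim$meth$prob[[sp]]]
      data.table::fwrite(out, file.path(out_dir, "truth",
                                        paste0("prob_", sp, ".tsv")),
                         sep = "\t")
    }
  }
  invisible(out_dir)
}

#' True homoeologous window classes from simulator probabilities
#'
#' Classifies every homoeologous 100-bp CG window of the truth site map by
#' the cDMR/hDMC rule applied to the TRUE methylation probabilities (not
#' read counts): the noise-free reference against which called classes are
#' scored.
#'
#' @param sim a [simulate_panel()] object.
#' @param tetraploid which tetraploid to classify against (default "wGh").
#' @param delta threshold on both deltas (default 0.6).
#' @param window window width (default 100).
#' @return data.table: win_id, true A/D/As/Ds window probabilities, class.
#' @export
true_homoeolog_classes <- function(sim, tetraploid = "wGh", delta = 0.6,
                                   window = 100L) {
  tm <- sim$truth$site_map[context == "CG"]
  nA <- nrow(sim$genomes$sites_A)
  p <- sim$meth$prob
  dt <- data.table::data.table(
    win_id = window_of(tm$chrom_As, tm$pos_As, window),
    pA = p$A[tm$idx_A], pD = p$D[tm$idx_D],
    pAs = p[[tetraploid]][tm$idx_A], pDs = p[[tetraploid]][nA + tm$idx_D])
  agg <- dt[, .(mCG_A = mean(pA), mCG_D = mean(pD), mCG_As = mean(pAs),
                mCG_Ds = mean(pDs), n_sites = .N), by = win_id]
  agg[, `:=`(diploid_delta = mCG_A - mCG_D,
             tetraploid_delta = mCG_As - mCG_Ds)]
  agg[, class := data.table::fcase(
    abs(diploid_delta) <= delta, "no_gate",
    abs(tetraploid_delta) > delta &
      sign(tetraploid_delta) == sign(diploid_delta), "cDMR",
    abs(tetraploid_delta) > delta &
      sign(tetraploid_delta) != sign(diploid_delta), "hDMC",
    default = "neither")]
  agg[]
}

#' Write a methylome panel as per-replicate CX reports
#'
#' @param panel a [methylome_panel()].
#' @param dir output directory.
#' @param species species id used in file names
#'   (`<species>_<rep>.cx.tsv`).
#' @export
write_panel_cx <- function(panel, dir, species = panel_species(panel)) {
  for (r in panel_replicates(panel)) {
    dt <- panel[, .(chrom, pos, strand, context)]
    dt[, `:=`(c = panel[[paste0("c_", r)]], t = panel[[paste0("t_", r)]])]
    if (paste0("g_", r) %in% names(panel)) dt[, g := panel[[paste0("g_", r)]]]
    write_cx_report(dt, file.path(dir, paste0(species, "_", r, ".cx.tsv")))
  }
  invisible(dir)
}

#' Read a simulated species panel directory back into memory
#'
#' @param dir a directory produced by [simulate_panel()].
#' @param species species ids to load (default: all CX files found).
#' @param genome optional genome for context validation.
#' @return named list of [methylome_panel()] objects.
#' @export
read_panel_dir <- function(dir, species = NULL, genome = NULL) {
  files <- list.files(file.path(dir, "methylomes"), pattern = "\\.cx\\.tsv$")
  info <- data.table::data.table(file = files)
  info[, `:=`(species = sub("_r[0-9]+\\.cx\\.tsv$", "", file),
              rep = sub("^.*_(r[0-9]+)\\.cx\\.tsv$", "\\1", file))]
  if (!is.null(species)) info <- info[info$species %in% species]
  out <- list()
  for (sp in unique(info$species)) {
    sub <- info[info$species == sp]
    reps <- stats::setNames(lapply(seq_len(nrow(sub)), function(i) {
      read_cx_report(file.path(dir, "methylomes", sub$file[i]), genome)
    }), sub$rep)
    out[[sp]] <- methylome_panel(reps, sp)
  }
  out
}
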