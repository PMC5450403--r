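#' Combine two panels into one over the union of their coordinates
#'
#' Used to build the diploid "parents" reference (A + D on the combined
#' diploid genome) matched to the hybrid panel.
#'
#' @param panel_a,panel_b [methylome_panel()] objects with identical
#'   replicate ids and disjoint chromosome sets.
#' @param species id for the combined panel.
#' @return a [methylome_panel()].
#' @export
combine_panels <- function(panel_a, panel_b, species = "parents") {
  assert_that(identical(panel_replicates(panel_a), panel_replicates(panel_b)),
              "panels must share replicate ids")
  out <- data.table::rbindlist(list(
    data.table::as.data.table(panel_a), data.table::as.data.table(panel_b)))
  data.table::setkeyv(out, c("chrom", "pos", "strand"))
  as_panel(out, species, panel_replicates(panel_a))
}

#' Run the complete comparative methylome workflow on a simulated panel
#'
#' Orchestrates the comparative workflow end to end: simulate the species
#' panel;
#' extract conserved regions and the quartet site map from the emitted
#' alignment blocks and genomes; confirm conserved cytosines by coverage
#' and guanine support; call DmCs (A vs D); call hybrid-vs-parent DMRs per
#' context and assess their maintenance across the wild allotetraploids;
#' build the CG methylation-divergence NJ tree with bootstrap; classify
#' gene-body methylation and compare the DmCG rate with Ks; classify
#' cDMR/hDMC windows and their expression bias; call methylation-shifted
#' genes; run the gene-loss contrast; and identify wild-vs-cultivated
#' epialleles.  When ground truth is available (always, for simulated
#' input) recovery metrics are added.  The report is reproducible: the same
#' seed yields a byte-identical report file.
#'
#' @param sim_cfg simulator configuration ([sim_config()]).
#' @param config analysis configuration ([pipeline_config()]).
#' @param seed master seed.
#' @param out_dir output directory (simulation files, stage outputs,
#'   report.json, report.md).
#' @param bootstrap_n phylogeny bootstrap replicates (default 200).
#' @param phylo_sites maximum conserved CG site columns used for the
#'   distance matrix (deterministic subsample; default 10000).
#' @return the report, invisibly (list).
#' @export
run_full_pipeline <- function(sim_cfg = sim_config(), config = pipeline_config(),
                              seed = 1L, out_dir = tempfile("polymeth_run_"),
                              bootstrap_n = 200L, phylo_sites = 10000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = unclass(config), sim_config = unclass(sim_cfg),
                 seed = as.integer(seed), stages = list())

  ## stage 1: simulate
  sim <- simulate_panel(sim_cfg, seed, out_dir = file.path(out_dir, "sim"))
  panels <- sim$panels
  report$stages$simulate <- list(
    n_species = length(panels),
    n_sites_diploid_A = nrow(sim$genomes$sites_A),
    n_conserved_truth = nrow(sim$truth$site_map))

  ## stage 2: conserved regions and site map from the emitted files
  read_blocks <- function(f) read_alignment_blocks(file.path(out_dir, "sim",
                                                             "alignments", f))
  keep <- function(b) select_conserved_regions(
    b, config$min_score_first, config$min_score_final, config$min_region_len)
  blocks_a <- keep(read_blocks("A_tet.maf"))
  blocks_d <- keep(read_blocks("D_tet.maf"))
  blocks_ad <- keep(read_blocks("A_D.maf"))
  gA <- sim$genomes$genome_A; gD <- sim$genomes$genome_D
  gT <- sim$genomes$genome_tet
  map_a_as <- build_site_map(blocks_a, list(A = gA, As = gT), "A", "As")
  map_d_ds <- build_site_map(blocks_d, list(D = gD, Ds = gT), "D", "Ds")
  map_a_d <- build_site_map(blocks_ad, list(A = gA, D = gD), "A", "D")
  qmap <- combine_quartet_map(map_a_as, map_d_ds, map_a_d)
  coords <- c(A = "A", D = "D", A2D5 = "AD",
              stats::setNames(rep("tet", length(SIM_TETRAPLOIDS)),
                              SIM_TETRAPLOIDS))
  qmap_ok <- confirm_conserved_cytosines(qmap, panels, coords,
                                         config$min_coverage)
  write_site_map(qmap_ok, file.path(out_dir, "site_map.tsv"))
  report$stages$conserved_sites <- list(
    n_regions = length(blocks_ad),
    n_map_sites = nrow(qmap),
    n_confirmed_sites = nrow(qmap_ok))

  ## stage 3: DmCs between the diploids
  dmcs <- call_dmcs(panels$A, panels$D, site_map = qmap_ok,
                    coords_a = "A", coords_b = "D",
                    delta = config$dmc_delta, alpha = config$dmc_p,
                    min_coverage = config$min_coverage)
  report$stages$dmc <- list(n_dmcs = nrow(dmcs),
                            n_skipped = attr(dmcs, "skipped"))

  ## stage 4: hybrid DMRs and maintenance
  parents <- combine_panels(panels$A, panels$D)
  wl <- function(panel, ctx, coords_sp) {
    window_levels(panel, ctx, config$dmr_window, config$min_coverage,
                  site_mean = config$window_site_mean,
                  site_map = qmap_ok, coords = coords_sp)
  }
  maint <- list(); hybrid_dmr_n <- list()
  for (ctx in VALID_CONTEXTS) {
    hyb_wl <- wl(panels$A2D5, ctx, "AD")
    par_wl <- wl(parents, ctx, "AD")
    dmrs_ctx <- call_dmrs_windows(hyb_wl, par_wl, ctx, config$dmr_alpha,
                                  if (ctx == "CHH") config$dmr_delta_chh else
                                    config$dmr_delta_cg_chg,
                                  config$dmr_window)
    tet_wls <- lapply(panels[SIM_WILD_TETRAPLOIDS], wl, ctx = ctx,
                      coords_sp = "tet")
    maint[[ctx]] <- assess_maintenance(dmrs_ctx, hyb_wl, par_wl, tet_wls, ctx,
                                       config$conservation_delta)
    hybrid_dmr_n[[ctx]] <- nrow(dmrs_ctx)
    write_dmr_bed(dmrs_ctx, file.path(out_dir,
                                      paste0("hybrid_dmrs_", ctx, ".bed")))
    if (ctx == "CG") hybrid_dmrs_cg <- dmrs_ctx
  }
  report$stages$hybrid_dmrs <- list(
    n_dmrs = hybrid_dmr_n,
    maintenance = lapply(maint, function(m) as.list(m$summary)))

  ## stage 5: methylation phylogeny
  phylo_panels <- panels[c("A", "D", SIM_TETRAPLOIDS)]
  vec <- methylation_vectors(phylo_panels, qmap_ok, coords, "CG",
                             config$min_coverage)
  if (ncol(vec) > phylo_sites) {
    set.seed(child_seed(seed, 40))
    vec <- vec[, sort(sample.int(ncol(vec), phylo_sites)), drop = FALSE]
  }
  boot <- bootstrap_support(vec, bootstrap_n, seed = child_seed(seed, 41))
  write_newick(boot$tree, file.path(out_dir, "methylome_tree.nwk"))
  true_tree <- ape::read.tree(text = sim$truth$tree)
  rf <- phangorn::RF.dist(ape::unroot(boot$tree), ape::unroot(true_tree))
  report$stages$phylogeny <- list(
    n_sites = ncol(vec), rf_distance_to_truth = rf,
    support = as.list(boot$support))

  ## stage 6: gene-body methylation vs sequence evolution
  genes_a <- sim_features(sim$genomes, "A")[kind == "gene"]
  body <- classify_body_methylation(
    panels$A, genes_a, alpha = config$body_binom_p,
    coverage_frac = config$ortholog_coverage_frac,
    nonconversion_rate = config$nonconversion_rate,
    min_coverage = config$min_coverage, method = config$site_call)
  dmc_a <- merge(dmcs[context == "CG", .(site_id = pos)],
                 qmap_ok[, .(site_id, chrom = chrom_A, pos = pos_A)],
                 by = "site_id")
  cg_census <- sim$genomes$sites_A[context == "CG", .(chrom, pos)]
  rates_dt <- dmcg_rate(genes_a, dmc_a, cg_census)
  ks_vals <- vapply(sim$truth$gene_meta$gene_id, function(g) {
    ks_ng86(sim$genomes$cds[[paste0(g, "_A")]],
            sim$genomes$cds[[paste0(g, "_D")]])$Ks
  }, numeric(1))
  ks_dt <- data.table::data.table(gene_id = sim$truth$gene_meta$gene_id,
                                  Ks = ks_vals)
  gb <- merge(merge(body[, .(gene_id, class)], rates_dt, by = "gene_id"),
              ks_dt, by = "gene_id")
  mode_of <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 3) return(NA_real_)
    d <- stats::density(x, from = 0)
    d$x[which.max(d$y)]
  }
  report$stages$gene_body <- list(
    n_methylated = sum(body$class == "methylated"),
    n_unmethylated = sum(body$class == "unmethylated"),
    dmcg_rate_mode_methylated = mode_of(gb[class == "methylated", dmcg_rate]),
    ks_mode_methylated = mode_of(gb[class == "methylated", Ks]),
    dmcg_rate_mode_unmethylated = mode_of(gb[class == "unmethylated", dmcg_rate]),
    ks_mode_unmethylated = mode_of(gb[class == "unmethylated", Ks]))

  ## stage 7: homoeolog cDMR/hDMC and expression bias
  hom <- classify_cdmr_hdmc(panels$A, panels$D, panels$wGh, qmap_ok,
                            config$homoeolog_delta, "CG", config$dmr_window,
                            config$min_coverage)
  bias <- pipeline_expression_bias(sim, hom, config)
  report$stages$homoeolog <- list(
    n_records = nrow(hom),
    n_cdmr = sum(hom$class == "cDMR"), n_hdmc = sum(hom$class == "hDMC"),
    biased_fraction_hdmc = bias$frac_hdmc,
    biased_fraction_cdmr = bias$frac_cdmr)

  ## stage 8: methylation-shifted genes and gene-loss contrast
  shifted <- call_methylation_shifted_genes(
    panels$wGh, panels$A, genes_a, qmap_ok, "A", config$shifted_gene_delta,
    "CG", config$min_coverage, config$ortholog_coverage_frac)
  genes_d <- sim_features(sim$genomes, "D")[kind == "gene"]
  loss <- gene_loss_contrast(sim$truth$spikes$lost_pairs, panels$A, panels$D,
                             genes_a, genes_d, config$min_coverage)
  report$stages$shifted_genes <- list(
    n_hyper = sum(shifted$class == "hyper"),
    n_hypo = sum(shifted$class == "hypo"),
    gene_loss_p = loss$p,
    gene_loss_mean_difference = loss$mean_difference)

  ## stage 9: epialleles
  dmr_gh <- call_dmrs_windows(wl(panels$cGh, "CG", "tet"),
                              wl(panels$wGh, "CG", "tet"), "CG",
                              config$dmr_alpha, config$dmr_delta_cg_chg)
  dmr_gb <- call_dmrs_windows(wl(panels$cGb, "CG", "tet"),
                              wl(panels$wGb, "CG", "tet"), "CG",
                              config$dmr_alpha, config$dmr_delta_cg_chg)
  genes_tet <- sim_features(sim$genomes, "tet")[kind == "gene"]
  epi <- identify_epialleles(dmr_gh, dmr_gb, genes_tet, config$promoter_len)
  feat_frac <- feature_overlap_fractions(dmr_gh, sim_features(sim$genomes, "tet"))
  report$stages$epialleles <- list(
    n_dmrs_gh = nrow(dmr_gh), n_dmrs_gb = nrow(dmr_gb),
    n_shared = sum(epi$summary$n_shared),
    n_candidate_genes = length(unique(epi$candidates$gene_id)),
    dmr_feature_fractions = stats::setNames(as.list(feat_frac$fraction),
                                            feat_frac$class))

  ## recovery metrics vs simulation truth
  report$recovery <- pipeline_recovery(sim, hybrid_dmrs_cg, maint$CG, hom,
                                       epi, shifted, rf)

  ## manifest with digests (relative paths, sorted: reproducible)
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, c("report.json", "report.md"))
  digests <- unname(tools::md5sum(file.path(out_dir, files)))
  report$manifest <- stats::setNames(as.list(digests), files)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "string")
  write_report_md(report, file.path(out_dir, "report.md"))
  invisible(report)
}

## biased-expression fractions among hDMC- vs cDMR-classified genes
pipeline_expression_bias <- function(sim, hom, config) {
  expr <- sim$expression
  genes_tet <- sim_features(sim$genomes, "tet")[kind == "gene"]
  if (nrow(hom) == 0) return(list(frac_hdmc = NA_real_, frac_cdmr = NA_real_))
  gr_win <- GenomicRanges::GRanges(
    sub(":[0-9]+$", "", hom$win_id),
    IRanges::IRanges(as.integer(sub("^.*:", "", hom$win_id)) + 1L,
                     as.integer(sub("^.*:", "", hom$win_id)) + 100L))
  gr_genes <- GenomicRanges::GRanges(genes_tet$chrom,
                                     IRanges::IRanges(genes_tet$start + 1L,
                                                      genes_tet$end))
  ov <- GenomicRanges::findOverlaps(gr_win, gr_genes)
  assoc <- data.table::data.table(
    win = S4Vectors::queryHits(ov),
    gene_id = sub("_(As|Ds)$", "", genes_tet$id[S4Vectors::subjectHits(ov)]))
  assoc <- assoc[!duplicated(assoc)]
  assoc[, class := hom$class[win]]
  assoc <- assoc[class %in% c("cDMR", "hDMC")]
  if (nrow(assoc) == 0) return(list(frac_hdmc = NA_real_, frac_cdmr = NA_real_))
  em <- function(sp, cp) {
    e <- expr[species == sp & copy == cp]
    m <- as.matrix(e[, .(rpkm_r1, rpkm_r2)])
    rownames(m) <- e$gene_id
    m
  }
  mats <- list(A = em("A", "A"), D = em("D", "D"),
               As = em("wGh", "As"), Ds = em("wGh", "Ds"))
  ids <- intersect(unique(assoc$gene_id), rownames(mats$A))
  mats <- lapply(mats, function(m) m[ids, , drop = FALSE])
  bias <- expression_bias(mats, config$bias_log2_shift, config$bias_alpha,
                          config$expr_pseudocount)
  assoc <- assoc[gene_id %in% ids]
  assoc[, biased := bias$biased[match(gene_id, bias$pair_id)]]
  list(frac_hdmc = mean(assoc[class == "hDMC", biased], na.rm = TRUE),
       frac_cdmr = mean(assoc[class == "cDMR", biased], na.rm = TRUE))
}

## recovery metrics against the simulator's ground truth
pipeline_recovery <- function(sim, hybrid_dmrs_cg, maint_cg, hom, epi,
                              shifted, rf) {
  tr <- sim$truth$spikes
  out <- list(rf_distance = rf)
  if (!is.null(tr$hybrid_dmrs) && nrow(tr$hybrid_dmrs) > 0) {
    spiked <- tr$hybrid_dmrs$win_id
    called <- hybrid_dmrs_cg$win_id
    out$hybrid_dmr_sensitivity <- mean(spiked %in% called)
    rec <- maint_cg$records[win_id %in% spiked]
    cons_cols <- paste0("cons_", SIM_WILD_TETRAPLOIDS)
    have <- intersect(cons_cols, names(rec))
    out$maintenance_estimate <- if (nrow(rec) > 0)
      mean(as.matrix(rec[, have, with = FALSE])) else NA_real_
    out$maintenance_frac_all <- if (nrow(rec) > 0)
      mean(rec$conserved_in_all) else NA_real_
    out$maintenance_frac_any <- if (nrow(rec) > 0)
      mean(rec$conserved_in_any) else NA_real_
  }
  if (!is.null(tr$cdmr_hdmc) && nrow(tr$cdmr_hdmc) > 0) {
    ## precision is scored against the noise-free probability classes so
    ## that drift-generated genuine cDMRs/hDMCs are not counted as errors
    truth_cls <- true_homoeolog_classes(sim)
    for (cl in c("cDMR", "hDMC")) {
      spiked <- tr$cdmr_hdmc[class == cl, win_id]
      true_wins <- truth_cls[class == cl, win_id]
      called <- hom[class == cl, win_id]
      out[[paste0(tolower(cl), "_recall")]] <- mean(spiked %in% called)
      out[[paste0(tolower(cl), "_precision")]] <- if (length(called) > 0)
        mean(called %in% true_wins) else NA_real_
    }
  }
  if (!is.null(tr$epialleles) && nrow(tr$epialleles) > 0) {
    shared <- tr$epialleles[scope == "shared", win_id]
    called_shared <- unique(epi$candidates$win_id)
    out$epiallele_shared_recall <- mean(shared %in% called_shared)
  }
  if (!is.null(tr$shifted_genes) && nrow(tr$shifted_genes) > 0) {
    for (d in c("hyper", "hypo")) {
      spiked <- tr$shifted_genes[direction == d, gene_id]
      called <- shifted[class == d, gene_id]
      out[[paste0("shifted_", d, "_recall")]] <- mean(spiked %in% called)
    }
  }
  out
}

write_report_md <- function(report, path) {
  lines <- c(
    "# polymeth pipeline report", "",
    sprintf("- seed: %d", report$seed),
    sprintf("- confirmed conserved cytosines: %d",
            report$stages$conserved_sites$n_confirmed_sites),
    sprintf("- DmCs (A vs D): %d", report$stages$dmc$n_dmcs),
    sprintf("- hybrid DMRs (CG/CHG/CHH): %s",
            paste(unlist(report$stages$hybrid_dmrs$n_dmrs), collapse = "/")),
    sprintf("- NJ tree RF distance to truth: %s",
            format(report$stages$phylogeny$rf_distance_to_truth)),
    sprintf("- cDMRs: %d, hDMCs: %d", report$stages$homoeolog$n_cdmr,
            report$stages$homoeolog$n_hdmc),
    sprintf("- biased fraction (hDMC vs cDMR): %.3f vs %.3f",
            report$stages$homoeolog$biased_fraction_hdmc,
            report$stages$homoeolog$biased_fraction_cdmr),
    sprintf("- shifted genes (hyper/hypo): %d/%d",
            report$stages$shifted_genes$n_hyper,
            report$stages$shifted_genes$n_hypo),
    sprintf("- epiallele candidate genes: %d",
            report$stages$epialleles$n_candidate_genes),
    "", "## Recovery vs simulation truth", "",
    vapply(names(report$recovery), function(k) {
      sprintf("- %s: %s", k, format(report$recovery[[k]]))
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
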