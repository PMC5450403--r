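#' Classify conserved DMRs (cDMRs) and homoeologous methylation changes (hDMCs)
#'
#' Windows with a strong diploid A-vs-D CG methylation difference
#' (|mCG_A - mCG_D| > delta) are classified by the behaviour of the
#' homoeologous As/Ds subgenome windows of the allotetraploid: a cDMR keeps
#' the diploid difference (same sign, |mCG_As - mCG_Ds| > delta), an hDMC
#' reverses it (opposite sign, |mCG_As - mCG_Ds| > delta); anything else is
#' `neither`.
#'
#' @param panel_a,panel_d diploid [methylome_panel()] objects (A and D).
#' @param tetraploid_panel allotetraploid panel (As+Ds chromosomes).
#' @param site_map quartet site map.
#' @param delta threshold on both deltas (default 0.6).
#' @param context methylation context (default "CG").
#' @param window window width (default 100).
#' @param min_coverage per-replicate site coverage floor (default 3).
#' @return data.table of records passing the diploid gate: win_id (on the
#'   As reference), mCG_A, mCG_D, mCG_As, mCG_Ds, diploid_delta,
#'   tetraploid_delta, class.
#' @export
classify_cdmr_hdmc <- function(panel_a, panel_d, tetraploid_panel, site_map,
                               delta = 0.6, context = "CG", window = 100L,
                               min_coverage = 3L) {
  hw <- homoeolog_window_levels(panel_a, panel_d, tetraploid_panel, site_map,
                                context, window, min_coverage)
  rec <- hw[elig_A & elig_D & elig_As & elig_Ds]
  rec[, `:=`(diploid_delta = mCG_A - mCG_D,
             tetraploid_delta = mCG_As - mCG_Ds)]
  delta_thr <- delta
  rec <- rec[abs(diploid_delta) > delta_thr]
  rec[, class := data.table::fcase(
    abs(tetraploid_delta) > delta_thr &
      sign(tetraploid_delta) == sign(diploid_delta), "cDMR",
    abs(tetraploid_delta) > delta_thr &
      sign(tetraploid_delta) != sign(diploid_delta), "hDMC",
    default = "neither")]
  rec[]
}

## window levels for A, D, As and Ds over homoeologous windows keyed on the
## As-subgenome coordinate.  Each site map row joins one As window; the A,
## D and Ds levels come from the same conserved sites via the map.
homoeolog_window_levels <- function(panel_a, panel_d, tetraploid_panel,
                                    site_map, context = "CG", window = 100L,
                                    min_coverage = 3L) {
  ctx_sel <- context
  sm <- site_map[context == ctx_sel]
  win_as <- window_of(sm$chrom_As, sm$pos_As, window)
  pooled <- list(
    A = panel_pooled_counts(panel_a),
    D = panel_pooled_counts(panel_d),
    tet = panel_pooled_counts(tetraploid_panel))
  min_sites <- if (context == "CHH") 16L else 4L
  out <- data.table::data.table(win_id = sort(unique(win_as)))
  ## the copy argument is ignored by map_coords for diploid coordinates;
  ## for the tetraploid it selects the subgenome
  sources <- list(A = list(panel = "A", coords = "A", copy = "As"),
                  D = list(panel = "D", coords = "D", copy = "As"),
                  As = list(panel = "tet", coords = "tet", copy = "As"),
                  Ds = list(panel = "tet", coords = "tet", copy = "Ds"))
  for (nm in names(sources)) {
    mc <- map_coords(sm, sources[[nm]]$coords, sources[[nm]]$copy)
    pp <- pooled[[sources[[nm]]$panel]]
    idx <- pp[mc, on = c("chrom", "pos", "strand"), which = TRUE]
    cvec <- ifelse(is.na(idx), NA_real_, pp$cs[idx])
    tvec <- ifelse(is.na(idx), NA_real_, pp$ts[idx])
    qual <- !is.na(cvec) & (cvec + tvec) >= min_coverage
    dt <- data.table::data.table(win_id = win_as, cvec = cvec, tvec = tvec,
                                 qual = qual)
    agg <- dt[qual == TRUE,
              .(lev = sum(cvec) / sum(cvec + tvec), n = .N), by = win_id]
    out <- merge(out, agg, by = "win_id", all.x = TRUE)
    data.table::setnames(out, c("lev", "n"),
                         c(paste0("mCG_", nm), paste0("n_", nm)))
    out[, paste0("elig_", nm) := !is.na(get(paste0("n_", nm))) &
          get(paste0("n_", nm)) >= min_sites]
  }
  out[]
}

panel_pooled_counts <- function(panel) {
  reps <- panel_replicates(panel)
  out <- panel[, .(chrom, pos, strand, context)]
  out[, cs := as.numeric(Reduce(`+`, lapply(reps, function(r) panel[[paste0("c_", r)]])))]
  out[, ts := as.numeric(Reduce(`+`, lapply(reps, function(r) panel[[paste0("t_", r)]])))]
  out
}

#' Call differentially expressed genes between two conditions
#'
#' A gene is a DEG when the fold change of pseudocounted group means exceeds
#' 2 (strictly) and the one-way ANOVA on the replicate expression values has
#' p < 0.01.
#'
#' @param expr_a,expr_b numeric matrices or data.frames (genes x
#'   replicates, >= 2 replicates each), same row order; rownames are gene
#'   ids.
#' @param fold_change fold-change threshold (default 2, strict).
#' @param alpha ANOVA p threshold (default 0.01).
#' @param pseudocount added to group means for the ratio (default 0.1).
#' @return data.table: gene_id, mean_a, mean_b, log2_fc, p_value, deg.
#' @export
call_degs <- function(expr_a, expr_b, fold_change = 2, alpha = 0.01,
                      pseudocount = 0.1) {
  ea <- as.matrix(expr_a); eb <- as.matrix(expr_b)
  assert_that(nrow(ea) == nrow(eb), "expression matrices differ in genes")
  assert_that(ncol(ea) >= 2 && ncol(eb) >= 2,
              "need >= 2 replicates per group")
  ids <- rownames(ea) %||% as.character(seq_len(nrow(ea)))
  res <- if (ncol(ea) == 2 && ncol(eb) == 2) {
    anova_2x2_vec(ea[, 1], ea[, 2], eb[, 1], eb[, 2])
  } else {
    ps <- vapply(seq_len(nrow(ea)), function(i) {
      one_way_anova(ea[i, ], eb[i, ])$p
    }, numeric(1))
    list(F = rep(NA_real_, nrow(ea)), p = ps)
  }
  m_a <- rowMeans(ea); m_b <- rowMeans(eb)
  l2fc <- log2((m_a + pseudocount) / (m_b + pseudocount))
  out <- data.table::data.table(gene_id = ids, mean_a = m_a, mean_b = m_b,
                                log2_fc = l2fc, p_value = res$p)
  out[, deg := abs(log2_fc) > log2(fold_change) & p_value < alpha]
  out[]
}

#' Homoeolog expression bias relative to the diploid ratio
#'
#' A homoeolog pair is biased when the tetraploid As/Ds expression ratio
#' departs from the diploid A/D ratio: the absolute log2 ratio shift exceeds
#' `log2_shift` and a one-way ANOVA on the per-replicate log ratios has
#' p < `alpha`.  Ratios are pseudocounted.
#'
#' @param expr matrix-like with one row per homoeolog pair and replicate
#'   columns for A, D, As, Ds; supply as a list of matrices
#'   `list(A =, D =, As =, Ds =)` (genes x replicates).
#' @param log2_shift ratio-shift threshold (default 1).
#' @param alpha replicate ANOVA threshold (default 0.05).
#' @param pseudocount RPKM pseudocount (default 0.1).
#' @return data.table: pair_id, log2_ratio_diploid, log2_ratio_tetraploid,
#'   shift, p_value, biased.  Pairs with a missing homoeolog value are
#'   excluded (biased = NA).
#' @export
expression_bias <- function(expr, log2_shift = 1, alpha = 0.05,
                            pseudocount = 0.1) {
  need <- c("A", "D", "As", "Ds")
  assert_that(all(need %in% names(expr)),
              "expr must contain matrices A, D, As, Ds")
  mats <- lapply(expr[need], as.matrix)
  n <- unique(vapply(mats, nrow, integer(1)))
  assert_that(length(n) == 1, "expression matrices differ in gene count")
  ids <- rownames(mats$A) %||% as.character(seq_len(n))
  lr_dip <- log2(mats$A + pseudocount) - log2(mats$D + pseudocount)
  lr_tet <- log2(mats$As + pseudocount) - log2(mats$Ds + pseudocount)
  res <- anova_2x2_vec(lr_tet[, 1], lr_tet[, 2], lr_dip[, 1], lr_dip[, 2])
  shift <- rowMeans(lr_tet) - rowMeans(lr_dip)
  out <- data.table::data.table(
    pair_id = ids,
    log2_ratio_diploid = rowMeans(lr_dip),
    log2_ratio_tetraploid = rowMeans(lr_tet),
    shift = shift, p_value = res$p)
  out[, biased := abs(shift) > log2_shift & p_value < alpha]
  miss <- rowSums(is.na(cbind(mats$A, mats$D, mats$As, mats$Ds))) > 0
  out[miss, biased := NA]
  out[]
}

#' Call hyper-/hypomethylated genes in the allotetraploid
#'
#' Gene-body CG methylation levels on conserved sites: a gene is
#' hypermethylated when the tetraploid body level exceeds the diploid
#' ortholog level by at least `delta`, hypomethylated at or below `-delta`.
#' Genes with under `coverage_frac` of their conserved body cytosines
#' callable in either species are excluded.
#'
#' @param tetraploid_panel allotetraploid panel.
#' @param diploid_panel diploid panel of the matching subgenome progenitor.
#' @param genes gene table in diploid coordinates (chrom, start, end, id).
#' @param site_map quartet site map.
#' @param diploid which diploid the genes/panel belong to ("A" or "D").
#' @param delta level-change threshold (default 0.6).
#' @param context default "CG".
#' @param min_coverage site coverage floor (default 3).
#' @param coverage_frac minimum callable fraction (default 0.4).
#' @return data.table: gene_id, level_diploid, level_tetraploid, delta,
#'   n_sites, class in {hyper, hypo, neither, excluded}.
#' @export
call_methylation_shifted_genes <- function(tetraploid_panel, diploid_panel,
                                           genes, site_map, diploid = "A",
                                           delta = 0.6, context = "CG",
                                           min_coverage = 3L,
                                           coverage_frac = 0.4) {
  genes <- data.table::as.data.table(genes)
  ctx_sel <- context
  sm <- site_map[context == ctx_sel]
  copy <- if (diploid == "A") "As" else "Ds"
  dip_mc <- map_coords(sm, diploid, copy)
  tet_mc <- map_coords(sm, "tet", copy)
  dp <- panel_pooled_counts(diploid_panel)
  tp <- panel_pooled_counts(tetraploid_panel)
  di <- dp[dip_mc, on = c("chrom", "pos", "strand")]
  ti <- tp[tet_mc, on = c("chrom", "pos", "strand")]
  sites <- data.table::data.table(
    chrom = dip_mc$chrom, pos = dip_mc$pos,
    c_dip = di$cs, t_dip = di$ts, c_tet = ti$cs, t_tet = ti$ts)
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  dt <- sites[S4Vectors::queryHits(ov)]
  dt[, gene_id := genes$id[S4Vectors::subjectHits(ov)]]
  dt[, ok := !is.na(c_dip) & !is.na(c_tet) &
       (c_dip + t_dip) >= min_coverage & (c_tet + t_tet) >= min_coverage]
  per <- dt[, .(
    n_total = .N, n_sites = sum(ok),
    level_diploid = sum(c_dip[ok]) / sum(c_dip[ok] + t_dip[ok]),
    level_tetraploid = sum(c_tet[ok]) / sum(c_tet[ok] + t_tet[ok])),
    by = gene_id]
  per[, delta := level_tetraploid - level_diploid]
  covfrac_thr <- coverage_frac; delta_thr <- delta
  per[, class := data.table::fcase(
    n_sites == 0 | n_sites / n_total < covfrac_thr, "excluded",
    delta >= delta_thr, "hyper",
    delta <= -delta_thr, "hypo",
    default = "neither")]
  out <- merge(data.table::data.table(gene_id = genes$id), per,
               by = "gene_id", all.x = TRUE)
  out[is.na(class), class := "excluded"]
  out[]
}

#' Compare gene-body non-CG methylation between lost and retained homoeologs
#'
#' For homoeolog pairs where one copy was lost in the allotetraploid but
#' both orthologs exist in the diploids, compares the diploid gene-body
#' non-CG (CHG + CHH) level of the lost copy against the retained copy with
#' a paired Wilcoxon signed-rank test.
#'
#' @param pairs data.table: pair_id, gene_a, gene_d, lost ("A" or "D").
#' @param panel_a,panel_d diploid panels.
#' @param genes_a,genes_d gene tables for the two diploids.
#' @param min_coverage site coverage floor (default 3).
#' @return list with per-pair levels, group means (lost vs retained), the
#'   mean paired difference, and the signed-rank p (with a low-power warning
#'   below 5 pairs).
#' @export
gene_loss_contrast <- function(pairs, panel_a, panel_d, genes_a, genes_d,
                               min_coverage = 3L) {
  pairs <- data.table::as.data.table(pairs)
  lv_a <- gene_noncg_levels(panel_a, genes_a, min_coverage)
  lv_d <- gene_noncg_levels(panel_d, genes_d, min_coverage)
  la <- lv_a$level[match(pairs$gene_a, lv_a$gene_id)]
  ld <- lv_d$level[match(pairs$gene_d, lv_d$gene_id)]
  lost <- ifelse(pairs$lost == "A", la, ld)
  retained <- ifelse(pairs$lost == "A", ld, la)
  ok <- !is.na(lost) & !is.na(retained)
  if (sum(ok) < 5) warning("fewer than 5 informative pairs; low power")
  p <- if (sum(ok) > 0) wilcoxon_signed_rank(lost[ok], retained[ok]) else NA_real_
  list(per_pair = data.table::data.table(pair_id = pairs$pair_id,
                                         lost_level = lost,
                                         retained_level = retained)[ok],
       mean_lost = mean(lost[ok]), mean_retained = mean(retained[ok]),
       mean_difference = mean(lost[ok] - retained[ok]), p = p,
       n_pairs = sum(ok))
}

gene_noncg_levels <- function(panel, genes, min_coverage = 3L) {
  genes <- data.table::as.data.table(genes)
  pp <- panel_pooled_counts(panel)
  pp <- pp[context %in% c("CHG", "CHH") & (cs + ts) >= min_coverage]
  gr_sites <- GenomicRanges::GRanges(pp$chrom,
                                     IRanges::IRanges(pp$pos + 1L, pp$pos + 1L))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  dt <- data.table::data.table(
    gene_id = genes$id[S4Vectors::subjectHits(ov)],
    cs = pp$cs[S4Vectors::queryHits(ov)],
    ts = pp$ts[S4Vectors::queryHits(ov)])
  dt[, .(level = sum(cs) / sum(cs + ts)), by = gene_id]
}

#' Identify putative epialleles from wild-vs-cultivated DMR sets
#'
#' Intersects the DMR sets of the two independent domestication comparisons
#' (cultivated-vs-wild in species 1 and species 2) by window identity on the
#' shared reference; shared same-direction DMRs that overlap a gene body or
#' (optionally) its 2-kb promoter yield epiallele candidates.  Also reports
#' the shared/specific window fractions per direction.
#'
#' @param dmrs_gh,dmrs_gb DMR records of the two comparisons (win_id,
#'   chrom, start, end, direction, context).
#' @param genes gene table on the shared reference (chrom, start, end,
#'   strand, id).
#' @param promoter_len promoter length upstream of the gene start (default
#'   2000; 0 disables promoter association).
#' @return list: `candidates` (gene_id, win_id, direction, context,
#'   association in {body, promoter}), `summary` (per direction: n in each
#'   set, n shared, shared fraction of the union).
#' @export
identify_epialleles <- function(dmrs_gh, dmrs_gb, genes, promoter_len = 2000L) {
  gh <- data.table::as.data.table(dmrs_gh)
  gb <- data.table::as.data.table(dmrs_gb)
  genes <- data.table::as.data.table(genes)
  shared <- merge(gh[, .(win_id, chrom, start, end, context, direction)],
                  gb[, .(win_id, direction)], by = "win_id",
                  suffixes = c("", "_gb"))
  shared <- shared[direction == direction_gb]
  summary <- data.table::rbindlist(lapply(c("hyper", "hypo"), function(d) {
    n1 <- sum(gh$direction == d); n2 <- sum(gb$direction == d)
    ns <- sum(shared$direction == d)
    un <- length(union(gh[direction == d, win_id], gb[direction == d, win_id]))
    data.table::data.table(direction = d, n_gh = n1, n_gb = n2, n_shared = ns,
                           shared_fraction = if (un > 0) ns / un else NA_real_)
  }))
  if (nrow(shared) == 0) {
    return(list(candidates = data.table::data.table(
      gene_id = character(), win_id = character(), direction = character(),
      context = character(), association = character()), summary = summary))
  }
  gr_dmr <- GenomicRanges::GRanges(shared$chrom,
                                   IRanges::IRanges(shared$start + 1L, shared$end))
  gr_body <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits_body <- GenomicRanges::findOverlaps(gr_dmr, gr_body)
  cand <- data.table::data.table(
    gene_id = genes$id[S4Vectors::subjectHits(hits_body)],
    win_id = shared$win_id[S4Vectors::queryHits(hits_body)],
    direction = shared$direction[S4Vectors::queryHits(hits_body)],
    context = shared$context[S4Vectors::queryHits(hits_body)],
    association = "body")
  if (promoter_len > 0) {
    prom_start <- ifelse(genes$strand == "-", genes$end,
                         pmax(0L, genes$start - promoter_len))
    prom_end <- ifelse(genes$strand == "-", genes$end + promoter_len,
                       genes$start)
    keep <- prom_end > prom_start
    gr_prom <- GenomicRanges::GRanges(genes$chrom[keep],
                                      IRanges::IRanges(prom_start[keep] + 1L,
                                                       prom_end[keep]))
    hits_prom <- GenomicRanges::findOverlaps(gr_dmr, gr_prom)
    cand_p <- data.table::data.table(
      gene_id = genes$id[keep][S4Vectors::subjectHits(hits_prom)],
      win_id = shared$win_id[S4Vectors::queryHits(hits_prom)],
      direction = shared$direction[S4Vectors::queryHits(hits_prom)],
      context = shared$context[S4Vectors::queryHits(hits_prom)],
      association = "promoter")
    cand <- data.table::rbindlist(list(cand, cand_p))
    cand <- cand[!duplicated(cand[, .(gene_id, win_id)])]
  }
  list(candidates = cand[], summary = summary)
}
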