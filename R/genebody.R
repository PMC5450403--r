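#' Call individual cytosines methylated against the non-conversion rate
#'
#' A site (pooled over replicates) is called methylated when the one-sided
#' binomial probability of observing its methylated read count under the
#' bisulfite non-conversion/error rate falls below `alpha`:
#' P(X >= c | coverage, nonconversion_rate) < alpha.  Sites under the
#' coverage floor return `NA` (excluded).  `method = "level:<x>"` instead
#' thresholds the methylation level at `<x>`.
#'
#' @param c_reads,t_reads pooled read counts (vectors allowed).
#' @param nonconversion_rate expected methylated-read fraction at an
#'   unmethylated site (default 0.005).
#' @param alpha binomial significance level (default 0.05).
#' @param min_coverage coverage floor (default 3).
#' @param method "binomial" (default) or "level:<threshold>".
#' @return logical vector (`NA` = excluded).
#' @examples
#' call_site_methylated(5, 0)   # TRUE: P ~ 3.1e-12
#' call_site_methylated(1, 19)  # FALSE: P(X>=1) ~ 0.095
#' @export
call_site_methylated <- function(c_reads, t_reads, nonconversion_rate = 0.005,
                                 alpha = 0.05, min_coverage = 3L,
                                 method = "binomial") {
  cov <- c_reads + t_reads
  out <- rep(NA, length(cov))
  ok <- cov >= min_coverage
  if (startsWith(method, "level:")) {
    thr <- as.numeric(sub("^level:", "", method))
    out[ok] <- (c_reads[ok] / cov[ok]) >= thr
  } else {
    p <- stats::pbinom(c_reads[ok] - 1, cov[ok], nonconversion_rate,
                       lower.tail = FALSE)
    out[ok] <- p < alpha
  }
  out
}

#' Genome-wide methylated-site fraction per context
#'
#' The background rates for the gene-body binomial test: the fraction of
#' callable sites (pooled coverage >= `min_coverage`) called methylated, per
#' context.
#'
#' @param panel a [methylome_panel()].
#' @inheritParams call_site_methylated
#' @return named numeric vector over CG/CHG/CHH.
#' @export
genome_background_rates <- function(panel, nonconversion_rate = 0.005,
                                    alpha = 0.05, min_coverage = 3L,
                                    method = "binomial") {
  reps <- panel_replicates(panel)
  cs <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("c_", r)]]))
  ts <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("t_", r)]]))
  calls <- call_site_methylated(cs, ts, nonconversion_rate, alpha,
                                min_coverage, method)
  tapply(calls, panel$context, function(x) mean(x, na.rm = TRUE))[VALID_CONTEXTS]
}

#' Classify gene-body CG methylation by binomial test
#'
#' Per gene and context, the number of methylated body cytosines m out of n
#' callable body cytosines is compared against the genome-wide methylated
#' fraction: P_context = P(X >= m | n, background).  A gene is CG
#' body-methylated when P_CG < alpha, CG body-unmethylated when
#' P_CG > 1 - alpha, and excluded when P_CHG < alpha or P_CHH < alpha (to
#' remove non-CG methylated genes), when fewer than `coverage_frac` of its
#' body cytosines are callable, or when it has no callable CG site.
#'
#' @param panel a [methylome_panel()].
#' @param genes feature table (chrom, start, end, strand, id) of gene
#'   bodies.
#' @param background_rates named per-context rates; computed from the panel
#'   via [genome_background_rates()] when NULL.
#' @param alpha binomial significance level (default 0.05).
#' @param coverage_frac minimum callable fraction of body cytosines
#'   (default 0.4).
#' @inheritParams call_site_methylated
#' @return data.table: gene_id, per-context m/n, P_CG/P_CHG/P_CHH,
#'   coverage_frac, class in {methylated, unmethylated, intermediate,
#'   excluded}.
#' @export
classify_body_methylation <- function(panel, genes, background_rates = NULL,
                                      alpha = 0.05, coverage_frac = 0.4,
                                      nonconversion_rate = 0.005,
                                      min_coverage = 3L, method = "binomial") {
  genes <- data.table::as.data.table(genes)
  if (is.null(background_rates)) {
    background_rates <- genome_background_rates(panel, nonconversion_rate,
                                                alpha, min_coverage, method)
  }
  reps <- panel_replicates(panel)
  cs <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("c_", r)]]))
  ts <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("t_", r)]]))
  sites <- panel[, .(chrom, pos, context)]
  sites[, meth := call_site_methylated(cs, ts, nonconversion_rate, alpha,
                                       min_coverage, method)]
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_genes)
  dt <- data.table::data.table(
    gene_id = genes$id[S4Vectors::subjectHits(ov)],
    context = sites$context[S4Vectors::queryHits(ov)],
    meth = sites$meth[S4Vectors::queryHits(ov)])
  per_gene <- dt[, .(
    n_total = .N,
    n_callable = sum(!is.na(meth)),
    m_cg = sum(meth[context == "CG"], na.rm = TRUE),
    n_cg = sum(!is.na(meth) & context == "CG"),
    m_chg = sum(meth[context == "CHG"], na.rm = TRUE),
    n_chg = sum(!is.na(meth) & context == "CHG"),
    m_chh = sum(meth[context == "CHH"], na.rm = TRUE),
    n_chh = sum(!is.na(meth) & context == "CHH")), by = gene_id]
  binom_upper <- function(m, n, p) {
    ifelse(n > 0, stats::pbinom(m - 1, n, p, lower.tail = FALSE), 1)
  }
  per_gene[, `:=`(
    P_CG = binom_upper(m_cg, n_cg, background_rates[["CG"]]),
    P_CHG = binom_upper(m_chg, n_chg, background_rates[["CHG"]]),
    P_CHH = binom_upper(m_chh, n_chh, background_rates[["CHH"]]),
    coverage_frac = n_callable / n_total)]
  covfrac_thr <- coverage_frac; alpha_thr <- alpha
  per_gene[, class := data.table::fcase(
    coverage_frac < covfrac_thr | n_cg == 0, "excluded",
    P_CHG < alpha_thr | P_CHH < alpha_thr, "excluded",
    P_CG < alpha_thr, "methylated",
    P_CG > 1 - alpha_thr, "unmethylated",
    default = "intermediate")]
  out <- merge(data.table::data.table(gene_id = genes$id), per_gene,
               by = "gene_id", all.x = TRUE)
  out[is.na(class), class := "excluded"]
  out[]
}

#' Gene-body DmCG rate per ortholog pair
#'
#' The epimutation-rate proxy: number of DmCGs falling in the gene body
#' divided by the total number of CG cytosines in the body.
#'
#' @param genes gene feature table (chrom, start, end, id) in the
#'   coordinates of `cg_sites` and `dmcs`.
#' @param dmcs DmC records with chrom/pos columns (CG context).
#' @param cg_sites table of all CG cytosines (chrom, pos), both strands.
#' @return data.table: gene_id, n_cg, n_dmcg, dmcg_rate (`NA` when the body
#'   has no CG site).
#' @export
dmcg_rate <- function(genes, dmcs, cg_sites) {
  genes <- data.table::as.data.table(genes)
  cg <- data.table::as.data.table(cg_sites)
  dm <- data.table::as.data.table(dmcs)
  count_in <- function(tab) {
    if (nrow(tab) == 0) return(integer(nrow(genes)))
    gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos + 1L, tab$pos + 1L))
    gg <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    GenomicRanges::countOverlaps(gg, gr)
  }
  out <- data.table::data.table(gene_id = genes$id,
                                n_cg = count_in(cg), n_dmcg = count_in(dm))
  out[, dmcg_rate := ifelse(n_cg > 0, n_dmcg / n_cg, NA_real_)]
  out[]
}

#' Methylation metaprofile over scaled gene bodies and absolute flanks
#'
#' Gene bodies are scaled to `body_bins` bins; 5' and 3' flanks of `flank`
#' bp are split into `flank_bins` absolute bins.  Minus-strand features are
#' reversed so bin 1 is always the distal 5' flank.  Bin values are
#' pooled-read methylation levels over all sites of all features in the
#' bin.
#'
#' @param panel a [methylome_panel()].
#' @param features stranded feature table (chrom, start, end, strand).
#' @param context CG/CHG/CHH.
#' @param flank flank length in bp (default 2000).
#' @param body_bins,flank_bins bin counts (default 20 each).
#' @param min_coverage per-site pooled coverage floor (default 3).
#' @return data.table: bin (1-based along 5'->3'), region (upstream, body,
#'   downstream), level.
#' @export
metaprofile <- function(panel, features, context, flank = 2000L,
                        body_bins = 20L, flank_bins = 20L, min_coverage = 3L) {
  check_context(context)
  ft <- data.table::as.data.table(features)
  reps <- panel_replicates(panel)
  cs <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("c_", r)]]))
  ts <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("t_", r)]]))
  cnt <- panel[, .(chrom, pos, context)]
  cnt[, `:=`(cs = cs, ts = ts)]
  ctx_sel <- context
  cnt <- cnt[context == ctx_sel & (cs + ts) >= min_coverage]
  total_bins <- 2L * flank_bins + body_bins
  acc_c <- numeric(total_bins); acc_t <- numeric(total_bins)
  for (i in seq_len(nrow(ft))) {
    fchrom <- ft$chrom[i]; fstart <- ft$start[i]; fend <- ft$end[i]
    minus <- identical(ft$strand[i], "-")
    s <- cnt[chrom == fchrom & pos >= fstart - flank & pos < fend + flank]
    if (nrow(s) == 0) next
    rel_bin <- integer(nrow(s))
    up <- s$pos < fstart
    dn <- s$pos >= fend
    body <- !up & !dn
    rel_bin[up] <- pmin(flank_bins - 1L,
                        ((s$pos[up] - (fstart - flank)) * flank_bins) %/% flank)
    rel_bin[body] <- flank_bins +
      pmin(body_bins - 1L,
           ((s$pos[body] - fstart) * body_bins) %/% max(1L, fend - fstart))
    rel_bin[dn] <- flank_bins + body_bins +
      pmin(flank_bins - 1L, ((s$pos[dn] - fend) * flank_bins) %/% flank)
    if (minus) rel_bin <- total_bins - 1L - rel_bin
    bb <- rel_bin + 1L
    add_c <- as.numeric(tapply(s$cs, factor(bb, seq_len(total_bins)), sum))
    add_t <- as.numeric(tapply(s$ts, factor(bb, seq_len(total_bins)), sum))
    add_c[is.na(add_c)] <- 0; add_t[is.na(add_t)] <- 0
    acc_c <- acc_c + add_c
    acc_t <- acc_t + add_t
  }
  region <- c(rep("upstream", flank_bins), rep("body", body_bins),
              rep("downstream", flank_bins))
  data.table::data.table(
    bin = seq_len(total_bins), region = region, context = context,
    level = ifelse(acc_c + acc_t > 0, acc_c / (acc_c + acc_t), NA_real_))
}

#' Intragenic vs intergenic TE methylation contrast
#'
#' TEs are partitioned by overlap with gene bodies; per-TE pooled
#' methylation levels are compared between the groups with a Wilcoxon
#' rank-sum test.
#'
#' @param panel a [methylome_panel()].
#' @param tes,genes feature tables (chrom, start, end).
#' @param context CG/CHG/CHH.
#' @param min_coverage per-site pooled coverage floor (default 3).
#' @return list with per-group means, their difference
#'   (intragenic - intergenic), per-TE levels, and the rank-sum p-value
#'   (`NA` with a warning when a group is empty).
#' @export
te_methylation_contrast <- function(panel, tes, genes, context,
                                    min_coverage = 3L) {
  check_context(context)
  tes <- data.table::as.data.table(tes)
  genes <- data.table::as.data.table(genes)
  reps <- panel_replicates(panel)
  cs <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("c_", r)]]))
  ts <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("t_", r)]]))
  sites <- panel[, .(chrom, pos, context)]
  sites[, `:=`(cs = cs, ts = ts)]
  ctx_sel <- context
  sites <- sites[context == ctx_sel & (cs + ts) >= min_coverage]
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  gr_te <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start + 1L, tes$end))
  gr_gn <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1L, genes$end))
  intragenic <- GenomicRanges::countOverlaps(gr_te, gr_gn) > 0
  ov <- GenomicRanges::findOverlaps(gr_sites, gr_te)
  per_te <- data.table::data.table(
    te = S4Vectors::subjectHits(ov),
    cs = sites$cs[S4Vectors::queryHits(ov)],
    ts = sites$ts[S4Vectors::queryHits(ov)])[,
      .(level = sum(cs) / sum(cs + ts)), by = te]
  per_te[, intragenic := intragenic[te]]
  g_in <- per_te[intragenic == TRUE, level]
  g_out <- per_te[intragenic == FALSE, level]
  if (length(g_in) == 0 || length(g_out) == 0) {
    warning("empty TE group; contrast undefined")
    return(list(mean_intragenic = NA_real_, mean_intergenic = NA_real_,
                difference = NA_real_, p = NA_real_, per_te = per_te[]))
  }
  p <- suppressWarnings(stats::wilcox.test(g_in, g_out)$p.value)
  list(mean_intragenic = mean(g_in), mean_intergenic = mean(g_out),
       difference = mean(g_in) - mean(g_out), p = p, per_te = per_te[])
}
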