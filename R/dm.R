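#' Call differentially methylated cytosines (DmCs) between two species
#'
#' Per site, replicate methylation levels (C/(C+T), coverage >= 3 in every
#' replicate of both species) are compared by one-way ANOVA; a DmC requires
#' an absolute difference of species mean levels of at least `delta` and
#' p < `alpha`.  Species means are means of replicate levels (the ANOVA's
#' unit of observation).  Sites missing a replicate are skipped and counted
#' in the `skipped` attribute, not treated as errors.
#'
#' @param panel_a,panel_b [methylome_panel()] objects with two replicates
#'   each.  Without a `site_map`, sites are joined on shared (chrom, pos,
#'   strand, context).
#' @param site_map optional quartet site map; with it, sites are joined via
#'   the mapped coordinates given by `coords_a`/`coords_b` and the subgenome
#'   `copy`.
#' @param coords_a,coords_b coordinate systems of the two panels ("A", "D",
#'   "tet", "AD"); used only with `site_map`.
#' @param copy which subgenome copy ("As"/"Ds") to compare when mapping.
#' @param delta minimum absolute mean difference (default 0.5).
#' @param alpha ANOVA p threshold (default 0.01).
#' @param min_coverage minimum reads per replicate (default 3).
#' @return data.table of DmC records (site key, replicate levels, species
#'   means, delta, F, p_value); attribute `skipped` counts sites dropped for
#'   coverage.  `context` column included.
#' @export
call_dmcs <- function(panel_a, panel_b, site_map = NULL,
                      coords_a = NULL, coords_b = NULL, copy = "As",
                      delta = 0.5, alpha = 0.01, min_coverage = 3L) {
  la <- site_levels_2rep(panel_a, min_coverage)
  lb <- site_levels_2rep(panel_b, min_coverage)
  if (is.null(site_map)) {
    key <- c("chrom", "pos", "strand", "context")
    m <- merge(la, lb, by = key, suffixes = c("_a", "_b"))
  } else {
    mca <- map_coords(site_map, coords_a, copy)
    mcb <- map_coords(site_map, coords_b, copy)
    ja <- la[mca, on = c("chrom", "pos", "strand"), nomatch = NULL]
    jb <- lb[mcb, on = c("chrom", "pos", "strand"), nomatch = NULL]
    m <- merge(ja[, .(site_id, context = i.context, l1_a = l1, l2_a = l2)],
               jb[, .(site_id, l1_b = l1, l2_b = l2)], by = "site_id")
    data.table::setnames(m, "site_id", "pos")  # site_id keys the records
    m[, `:=`(chrom = "map", strand = "+")]
  }
  total <- nrow(m)
  cc <- stats::complete.cases(m[, .(l1_a, l2_a, l1_b, l2_b)])
  m <- m[cc]
  res <- anova_2x2_vec(m$l1_a, m$l2_a, m$l1_b, m$l2_b)
  m[, `:=`(mean_a = (l1_a + l2_a) / 2, mean_b = (l1_b + l2_b) / 2)]
  m[, `:=`(delta = mean_a - mean_b, F = res$F, p_value = res$p)]
  delta_thr <- delta; alpha_thr <- alpha
  out <- m[abs(delta) >= delta_thr & p_value < alpha_thr]
  data.table::setattr(out, "skipped", total - sum(cc))
  out[]
}

## per-site replicate levels for a two-replicate panel (NA below coverage)
site_levels_2rep <- function(panel, min_coverage = 3L) {
  reps <- panel_replicates(panel)
  assert_that(length(reps) == 2,
              "the statistical operations require exactly two replicates (got %d)",
              length(reps))
  out <- panel[, .(chrom, pos, strand, context)]
  out[, l1 := site_level(panel[[paste0("c_", reps[1])]],
                         panel[[paste0("t_", reps[1])]], min_coverage)]
  out[, l2 := site_level(panel[[paste0("c_", reps[2])]],
                         panel[[paste0("t_", reps[2])]], min_coverage)]
  out
}

#' Per-replicate 100-bp window methylation levels with eligibility
#'
#' Windows are consecutive tiles (default 100 bp).  A cytosine qualifies if
#' it has the requested context and coverage >= `min_coverage` in every
#' replicate; a window is eligible when it contains at least 4 (CG/CHG) or
#' 16 (CHH) qualifying cytosines.  The replicate window level is the
#' pooled-read mean sum(C)/sum(C+T) over qualifying sites (coverage-weighted);
#' set `site_mean = TRUE` for the unweighted mean of site levels.
#'
#' @param panel a [methylome_panel()].
#' @param context one of CG/CHG/CHH.
#' @param window window width in bp (default 100).
#' @param min_coverage minimum reads per replicate per site (default 3).
#' @param min_sites override the context-dependent eligibility count.
#' @param site_mean use mean of site levels instead of pooled reads.
#' @param site_map,coords optional: compute windows on the allotetraploid
#'   reference via a quartet map; window ids then come from the mapped
#'   As/Ds coordinates and the panel is looked up at its own coordinates.
#' @return data.table: win_id, chrom, start, n_sites, eligible, l1, l2.
#' @export
window_levels <- function(panel, context, window = 100L, min_coverage = 3L,
                          min_sites = NULL, site_mean = FALSE,
                          site_map = NULL, coords = NULL) {
  check_context(context)
  min_sites <- min_sites %||% (if (context == "CHH") 16L else 4L)
  reps <- panel_replicates(panel)
  assert_that(length(reps) == 2, "window_levels requires two replicates")
  ctx_sel <- context
  if (is.null(site_map)) {
    sites <- panel[context == ctx_sel,
                   c("chrom", "pos", "strand",
                     paste0(c("c_", "t_"), rep(reps, each = 2))), with = FALSE]
    sites[, win_id := window_of(chrom, pos, window)]
  } else {
    sites <- data.table::rbindlist(lapply(c("As", "Ds"), function(cp) {
      mc <- map_coords(site_map, coords, cp)
      mc <- mc[context == ctx_sel]
      ref_chrom <- site_map[[paste0("chrom_", cp)]][match(mc$site_id, site_map$site_id)]
      ref_pos <- site_map[[paste0("pos_", cp)]][match(mc$site_id, site_map$site_id)]
      j <- panel[mc, on = c("chrom", "pos", "strand"), nomatch = NULL,
                 c("chrom", "pos", "strand",
                   paste0(c("c_", "t_"), rep(reps, each = 2))), with = FALSE]
      hit <- panel[mc, on = c("chrom", "pos", "strand"), which = TRUE]
      keep <- !is.na(hit)
      j[, win_id := window_of(ref_chrom[keep], ref_pos[keep], window)]
      j
    }))
  }
  if (nrow(sites) == 0) {
    return(data.table::data.table(win_id = character(), chrom = character(),
                                  start = integer(), n_sites = integer(),
                                  eligible = logical(), l1 = numeric(),
                                  l2 = numeric()))
  }
  c1 <- sites[[paste0("c_", reps[1])]]; t1 <- sites[[paste0("t_", reps[1])]]
  c2 <- sites[[paste0("c_", reps[2])]]; t2 <- sites[[paste0("t_", reps[2])]]
  qual <- (c1 + t1) >= min_coverage & (c2 + t2) >= min_coverage
  sites <- sites[qual]
  c1 <- c1[qual]; t1 <- t1[qual]; c2 <- c2[qual]; t2 <- t2[qual]
  if (site_mean) {
    sites[, `:=`(lv1 = c1 / (c1 + t1), lv2 = c2 / (c2 + t2))]
    agg <- sites[, .(n_sites = .N, l1 = mean(lv1), l2 = mean(lv2)), by = win_id]
  } else {
    sites[, `:=`(cc1 = c1, tt1 = t1, cc2 = c2, tt2 = t2)]
    agg <- sites[, .(n_sites = .N,
                     l1 = sum(cc1) / sum(cc1 + tt1),
                     l2 = sum(cc2) / sum(cc2 + tt2)), by = win_id]
  }
  agg[, eligible := n_sites >= min_sites]
  agg[, chrom := sub(":[0-9]+$", "", win_id)]
  agg[, start := as.integer(sub("^.*:", "", win_id))]
  data.table::setcolorder(agg, c("win_id", "chrom", "start", "n_sites",
                                 "eligible", "l1", "l2"))
  data.table::setorderv(agg, c("chrom", "start"))
  agg[]
}

#' Call DMRs from two window-level tables
#'
#' For each window eligible in both species, one-way ANOVA on the four
#' replicate window levels; a DMR requires p < `alpha` and an absolute
#' group-mean difference of at least the context cut-off (0.5 for CG/CHG,
#' 0.2 for CHH).  Direction is `hyper` when the first group is higher.
#'
#' @param wl_a,wl_b window-level tables ([window_levels()]), first group =
#'   `wl_a`.
#' @param context CG/CHG/CHH (sets the default delta cut-off).
#' @param alpha ANOVA p threshold (default 0.05).
#' @param delta_cutoff override the context cut-off.
#' @param window window width used to derive `end` (default 100).
#' @return data.table of DMR records; attribute `n_eligible` gives the
#'   number of windows tested.
#' @export
call_dmrs_windows <- function(wl_a, wl_b, context, alpha = 0.05,
                              delta_cutoff = NULL, window = 100L) {
  check_context(context)
  delta_cutoff <- delta_cutoff %||% (if (context == "CHH") 0.2 else 0.5)
  m <- merge(wl_a[eligible == TRUE], wl_b[eligible == TRUE],
             by = c("win_id", "chrom", "start"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0) {
    warning("zero eligible windows shared between the two groups")
    out <- data.table::data.table(
      win_id = character(), chrom = character(), start = integer(),
      end = integer(), context = character(), l1_a = numeric(),
      l2_a = numeric(), l1_b = numeric(), l2_b = numeric(),
      mean_a = numeric(), mean_b = numeric(), delta = numeric(),
      F = numeric(), p_value = numeric(), direction = character())
    data.table::setattr(out, "n_eligible", 0L)
    return(out)
  }
  res <- anova_2x2_vec(m$l1_a, m$l2_a, m$l1_b, m$l2_b)
  m[, `:=`(mean_a = (l1_a + l2_a) / 2, mean_b = (l1_b + l2_b) / 2)]
  m[, `:=`(delta = mean_a - mean_b, F = res$F, p_value = res$p)]
  alpha_thr <- alpha; delta_thr <- delta_cutoff; ctx_sel <- context
  out <- m[p_value < alpha_thr & abs(delta) >= delta_thr]
  out[, `:=`(end = start + as.integer(window), context = ctx_sel,
             direction = ifelse(delta > 0, "hyper", "hypo"))]
  data.table::setcolorder(out, c("win_id", "chrom", "start", "end", "context"))
  keep_cols <- c("win_id", "chrom", "start", "end", "context",
                 "l1_a", "l2_a", "l1_b", "l2_b", "mean_a", "mean_b",
                 "delta", "F", "p_value", "direction")
  out <- out[, keep_cols, with = FALSE]
  data.table::setorderv(out, c("chrom", "start"))
  data.table::setattr(out, "n_eligible", nrow(m))
  out[]
}

#' @rdname call_dmrs_windows
#' @param panel_a,panel_b panels sharing a coordinate system; convenience
#'   wrapper that computes window levels and calls
#'   [call_dmrs_windows()].
#' @param min_coverage,site_mean passed to [window_levels()].
#' @export
call_dmrs <- function(panel_a, panel_b, context, window = 100L, alpha = 0.05,
                      delta_cutoff = NULL, min_coverage = 3L, site_mean = FALSE) {
  wl_a <- window_levels(panel_a, context, window, min_coverage,
                        site_mean = site_mean)
  wl_b <- window_levels(panel_b, context, window, min_coverage,
                        site_mean = site_mean)
  call_dmrs_windows(wl_a, wl_b, context, alpha, delta_cutoff, window)
}

#' Assess maintenance of hybrid-induced DMRs across allotetraploids
#'
#' A hybrid DMR (hybrid vs. parent) is conserved in a tetraploid iff the
#' tetraploid-minus-parent window delta has the same sign as the hybrid
#' delta and absolute value >= the context threshold (0.4 for CG/CHG, 0.1
#' for CHH).  Reports per-DMR flags, the fractions conserved in >= 1 and in
#' all tetraploids, and an upper-tail hypergeometric enrichment p-value
#' against the background rate of such same-sign changes among all windows
#' eligible everywhere.
#'
#' @param hybrid_dmrs DMR records from the hybrid-vs-parent comparison.
#' @param hybrid_wl,parent_wl window-level tables for hybrid and parent
#'   (the background universe).
#' @param tetraploid_wls named list of window-level tables, one per
#'   tetraploid, on the same windows.
#' @param context CG/CHG/CHH.
#' @param thresholds named conserved-DMR thresholds (default c(CG=0.4,
#'   CHG=0.4, CHH=0.1)).
#' @return list with `records` (per-DMR flags), `summary` (fractions and
#'   enrichment p-values per direction), and `n_ineligible` (DMR x
#'   tetraploid combinations lacking an eligible window, counted as not
#'   conserved).
#' @export
assess_maintenance <- function(hybrid_dmrs, hybrid_wl, parent_wl,
                               tetraploid_wls, context,
                               thresholds = c(CG = 0.4, CHG = 0.4, CHH = 0.1)) {
  check_context(context)
  thr <- thresholds[[context]]
  universe <- merge(hybrid_wl[eligible == TRUE, .(win_id, hl1 = l1, hl2 = l2)],
                    parent_wl[eligible == TRUE, .(win_id, pl1 = l1, pl2 = l2)],
                    by = "win_id")
  universe[, `:=`(hyb_delta = (hl1 + hl2) / 2 - (pl1 + pl2) / 2,
                  parent_mean = (pl1 + pl2) / 2)]
  for (tp in names(tetraploid_wls)) {
    tw <- tetraploid_wls[[tp]][eligible == TRUE,
                               .(win_id, tmean = (l1 + l2) / 2)]
    universe <- merge(universe, tw, by = "win_id", all.x = TRUE)
    tdelta <- universe$tmean - universe$parent_mean
    cons <- !is.na(tdelta) & abs(tdelta) >= thr &
      sign(tdelta) == sign(universe$hyb_delta)
    universe[, paste0("cons_", tp) := cons]
    universe[, paste0("inel_", tp) := is.na(tdelta)]
    universe[, tmean := NULL]
  }
  cons_cols <- paste0("cons_", names(tetraploid_wls))
  inel_cols <- paste0("inel_", names(tetraploid_wls))
  cons_mat <- as.matrix(universe[, cons_cols, with = FALSE])
  universe[, `:=`(conserved_in_any = rowSums(cons_mat) >= 1,
                  conserved_in_all = rowSums(cons_mat) == length(tetraploid_wls))]
  in_dmr <- universe$win_id %in% hybrid_dmrs$win_id
  rec <- universe[in_dmr]
  n_inelig <- sum(as.matrix(universe[, inel_cols, with = FALSE])[in_dmr, , drop = FALSE])
  ## enrichment: draws = DMR windows, category = windows conserved-in-any
  ## (resp. all) among all eligible windows
  N <- nrow(universe); n <- nrow(rec)
  summary <- data.table::data.table(
    context = context,
    n_dmrs = n,
    frac_any = if (n > 0) mean(rec$conserved_in_any) else NA_real_,
    frac_all = if (n > 0) mean(rec$conserved_in_all) else NA_real_,
    p_any = hypergeometric_enrichment(sum(rec$conserved_in_any), n,
                                      sum(universe$conserved_in_any), N),
    p_all = hypergeometric_enrichment(sum(rec$conserved_in_all), n,
                                      sum(universe$conserved_in_all), N))
  dir_sum <- merge(rec,
                   hybrid_dmrs[, .(win_id, direction)], by = "win_id")[,
    .(n = .N, frac_any = mean(conserved_in_any), frac_all = mean(conserved_in_all)),
    by = direction]
  list(records = rec[], summary = summary, by_direction = dir_sum[],
       n_ineligible = n_inelig)
}

#' Fraction of DMRs per genomic feature class
#'
#' Each DMR is assigned by its midpoint to exactly one class with precedence
#' gene body > TE > intergenic, so the fractions partition the DMR set.
#'
#' @param dmrs DMR records (chrom, start, end).
#' @param features feature table (chrom, start, end, kind with kinds `gene`,
#'   `TE_classI`, `TE_classII`).
#' @return data.table with class, n and fraction (summing to 1).
#' @export
feature_overlap_fractions <- function(dmrs, features) {
  dmrs <- data.table::as.data.table(dmrs)
  if (nrow(dmrs) == 0) {
    return(data.table::data.table(class = c("gene", "TE", "intergenic"),
                                  n = 0L, fraction = NA_real_))
  }
  mid <- as.integer((dmrs$start + dmrs$end) %/% 2)
  gr_mid <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(mid + 1L, mid + 1L))
  ft <- data.table::as.data.table(features)
  cls <- rep("intergenic", nrow(dmrs))
  te <- ft[kind %in% c("TE_classI", "TE_classII")]
  if (nrow(te) > 0) {
    gr_te <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start + 1L, te$end))
    cls[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_mid, gr_te))] <- "TE"
  }
  gn <- ft[kind == "gene"]
  if (nrow(gn) > 0) {
    gr_gn <- GenomicRanges::GRanges(gn$chrom, IRanges::IRanges(gn$start + 1L, gn$end))
    cls[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_mid, gr_gn))] <- "gene"
  }
  out <- data.table::data.table(class = factor(cls, c("gene", "TE", "intergenic")))
  out <- out[, .(n = .N), by = class][order(class)]
  out <- merge(data.table::data.table(class = factor(c("gene", "TE", "intergenic"),
                                                     c("gene", "TE", "intergenic"))),
               out, by = "class", all.x = TRUE)
  out[is.na(n), n := 0L]
  out[, fraction := n / sum(n)]
  out[, class := as.character(class)]
  out[]
}
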