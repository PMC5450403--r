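#' Methylome panels: per-species replicate cytosine count tables
#'
#' A `MethylomePanel` holds, for one species, per-cytosine bisulfite counts
#' for all biological replicates over a shared site key (chrom, 0-based pos,
#' strand, context).  Counts are stored wide: columns `c_<rep>`, `t_<rep>`
#' and optionally `g_<rep>` (complementary-strand guanine reads confirming
#' the cytosine).  All coordinates are 0-based half-open internally.
#'
#' @param replicates named list of per-replicate site-count tables as
#'   returned by [read_cx_report()] (columns chrom, pos, strand, context,
#'   c, t and optionally g).
#' @param species species identifier.
#' @return a `MethylomePanel` (data.table with attributes `species` and
#'   `replicates`).
#' @export
methylome_panel <- function(replicates, species) {
  assert_that(length(replicates) >= 1, "need at least one replicate")
  if (is.null(names(replicates)) || any(names(replicates) == "")) {
    names(replicates) <- paste0("r", seq_along(replicates))
  }
  key <- c("chrom", "pos", "strand", "context")
  base <- NULL
  for (rep_id in names(replicates)) {
    dt <- data.table::as.data.table(replicates[[rep_id]])
    assert_that(all(key %in% names(dt)),
                "replicate '%s' lacks site key columns", rep_id)
    cols <- intersect(c("c", "t", "g"), names(dt))
    dt <- dt[, c(key, cols), with = FALSE]
    data.table::setnames(dt, cols, paste0(cols, "_", rep_id))
    if (is.null(base)) {
      base <- dt
    } else {
      assert_that(nrow(base) == nrow(dt),
                  "replicate '%s' has a different site set", rep_id)
      base <- merge(base, dt, by = key, all = FALSE)
      assert_that(nrow(base) == nrow(dt),
                  "replicate '%s' has a different site set", rep_id)
    }
  }
  data.table::setkeyv(base, c("chrom", "pos", "strand"))
  data.table::setattr(base, "species", species)
  data.table::setattr(base, "replicates", names(replicates))
  data.table::setattr(base, "class", c("MethylomePanel", class(base)))
  base
}

#' @export
print.MethylomePanel <- function(x, ...) {
  cat(sprintf("MethylomePanel '%s': %d sites, replicates: %s\n",
              attr(x, "species"), nrow(x),
              paste(attr(x, "replicates"), collapse = ", ")))
  NextMethod()
}

panel_species <- function(panel) attr(panel, "species")
panel_replicates <- function(panel) attr(panel, "replicates")

## keep MethylomePanel attributes through data.table subsetting
as_panel <- function(dt, species, replicates) {
  data.table::setattr(dt, "species", species)
  data.table::setattr(dt, "replicates", replicates)
  if (!inherits(dt, "MethylomePanel")) {
    data.table::setattr(dt, "class", c("MethylomePanel", class(dt)))
  }
  dt
}

## long view: one row per site x replicate with c, t, coverage, level
panel_long <- function(panel, min_coverage = 3L) {
  reps <- panel_replicates(panel)
  out <- data.table::rbindlist(lapply(reps, function(r) {
    dt <- panel[, .(chrom, pos, strand, context,
                    c = get(paste0("c_", r)), t = get(paste0("t_", r)))]
    dt[, replicate := r]
    dt
  }))
  out[, coverage := c + t]
  out[, level := ifelse(coverage >= min_coverage, c / coverage, NA_real_)]
  out[]
}

## per-site pooled (all replicates, coverage-weighted) level
panel_pooled_level <- function(panel, min_coverage = 3L) {
  reps <- panel_replicates(panel)
  cs <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("c_", r)]]))
  ts <- Reduce(`+`, lapply(reps, function(r) panel[[paste0("t_", r)]]))
  cov <- cs + ts
  out <- panel[, .(chrom, pos, strand, context)]
  out[, coverage := cov]
  out[, level := ifelse(cov >= min_coverage, cs / cov, NA_real_)]
  out[]
}
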