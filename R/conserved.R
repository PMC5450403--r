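#' Select conserved regions from scored alignment blocks
#'
#' Reproduces the alignment-filtering contract used to define conserved
#' regions between genomes: blocks must pass a first-pass score, be the
#' unique best (1-to-1) alignment for both their source and target
#' intervals, reach a final score, and span a minimum length.  When two kept
#' candidates overlap on either side, the higher score wins; equal scores
#' are broken deterministically by (source chrom, start).
#'
#' @param blocks list of alignment blocks ([read_alignment_blocks()]).
#' @param min_score_first first-pass score threshold (block score must
#'   exceed it; default 500).
#' @param min_score_final final score threshold (default 2000).
#' @param min_len minimum source-interval length in bp (default 2000).
#' @return the kept blocks, ordered by (source chrom, start).
#' @export
select_conserved_regions <- function(blocks, min_score_first = 500,
                                     min_score_final = 2000, min_len = 2000) {
  assert_that(all(vapply(blocks, function(b) is.finite(b$score %||% NA_real_),
                         logical(1))),
              "alignment blocks without scores")
  blocks <- Filter(function(b) b$score > min_score_first, blocks)
  if (length(blocks) == 0) return(list())
  ord <- order(-vapply(blocks, `[[`, numeric(1), "score"),
               vapply(blocks, function(b) b$src$chrom, character(1)),
               vapply(blocks, function(b) as.numeric(b$src$start), numeric(1)))
  blocks <- blocks[ord]
  kept <- list()
  for (b in blocks) {
    clash <- any(vapply(kept, function(k) {
      (k$src$chrom == b$src$chrom &&
         b$src$start < k$src$end && k$src$start < b$src$end) ||
        (k$tgt$chrom == b$tgt$chrom &&
           b$tgt$start < k$tgt$end && k$tgt$start < b$tgt$end)
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- b
  }
  kept <- Filter(function(b) b$score > min_score_final &&
                   (b$src$end - b$src$start) >= min_len, kept)
  kept[order(vapply(kept, function(b) b$src$chrom, character(1)),
             vapply(kept, function(b) as.numeric(b$src$start), numeric(1)))]
}

#' Build a pairwise conserved-cytosine site map
#'
#' A position enters the map only if it is a cytosine of identical context
#' in both genomes, honoring strand flips for reverse-oriented blocks (a +
#' strand source cytosine in a `-` block pairs with a `-` strand target
#' cytosine).
#'
#' @param regions conserved alignment blocks ([select_conserved_regions()]).
#' @param genomes named list with the two genome sequences; names must
#'   include `src_name` and `tgt_name`.
#' @param src_name,tgt_name genome labels for the block source/target sides.
#' @return data.table with one row per conserved cytosine: context, and
#'   `chrom_<name>`, `pos_<name>`, `strand_<name>` for both genomes.
#' @export
build_site_map <- function(regions, genomes, src_name = "src", tgt_name = "tgt") {
  assert_that(all(c(src_name, tgt_name) %in% names(genomes)),
              "genomes list must contain '%s' and '%s'", src_name, tgt_name)
  src_chroms <- names(genome_as_char(genomes[[src_name]]))
  for (b in regions) {
    assert_that(b$src$chrom %in% src_chroms,
                "region references unknown chromosome '%s'", b$src$chrom)
  }
  corr <- data.table::rbindlist(lapply(regions, function(b) {
    data.table::data.table(
      src_chrom = b$src$chrom, src_pos = b$pairs[, "src_pos"],
      tgt_chrom = b$tgt$chrom, tgt_pos = b$pairs[, "tgt_pos"],
      flip = b$tgt$strand == "-")
  }))
  if (is.null(corr) || nrow(corr) == 0) return(empty_site_map(src_name, tgt_name))
  ## each strand of the source cytosine maps to tgt strand, flipped in
  ## reverse-oriented blocks
  out <- data.table::rbindlist(lapply(c("+", "-"), function(st) {
    tgt_st <- ifelse(corr$flip, if (st == "+") "-" else "+", st)
    ctx_src <- derive_context(genomes[[src_name]], corr$src_chrom, corr$src_pos,
                              rep(st, nrow(corr)))
    ctx_tgt <- derive_context(genomes[[tgt_name]], corr$tgt_chrom, corr$tgt_pos,
                              tgt_st)
    keep <- !is.na(ctx_src) & !is.na(ctx_tgt) & ctx_src == ctx_tgt
    data.table::data.table(
      context = ctx_src[keep],
      a_chrom = corr$src_chrom[keep], a_pos = corr$src_pos[keep],
      a_strand = st,
      b_chrom = corr$tgt_chrom[keep], b_pos = corr$tgt_pos[keep],
      b_strand = tgt_st[keep])
  }))
  data.table::setnames(out,
    c("a_chrom", "a_pos", "a_strand", "b_chrom", "b_pos", "b_strand"),
    c(paste0(c("chrom_", "pos_", "strand_"), src_name),
      paste0(c("chrom_", "pos_", "strand_"), tgt_name)))
  data.table::setorderv(out, paste0(c("chrom_", "pos_", "strand_"), src_name))
  out[]
}

empty_site_map <- function(src_name, tgt_name) {
  out <- data.table::data.table(context = character(),
                                a = character(), b = integer(), c = character(),
                                d = character(), e = integer(), f = character())
  data.table::setnames(out, c("context",
    paste0(c("chrom_", "pos_", "strand_"), src_name),
    paste0(c("chrom_", "pos_", "strand_"), tgt_name)))
  out
}

#' Join pairwise site maps into a homoeologous quartet map
#'
#' Combines the three pairwise conserved-cytosine maps A<->As, D<->Ds and
#' A<->D into one table giving, for every cytosine conserved across all four
#' genome copies, its coordinate in the diploid A and D genomes and in the
#' As and Ds subgenomes of the allotetraploid reference.
#'
#' @param map_a_as site map from diploid A to the As subgenome
#'   (`build_site_map(..., src_name = "A", tgt_name = "As")`).
#' @param map_d_ds site map from diploid D to the Ds subgenome.
#' @param map_a_d site map between the diploid genomes.
#' @return data.table with `site_id`, context, and chrom/pos/strand for A,
#'   D, As and Ds.
#' @export
combine_quartet_map <- function(map_a_as, map_d_ds, map_a_d) {
  key_a <- c("chrom_A", "pos_A", "strand_A")
  q <- merge(map_a_d, map_a_as, by = c("context", key_a))
  q <- merge(q, map_d_ds, by = c("context", "chrom_D", "pos_D", "strand_D"))
  data.table::setorderv(q, c("chrom_As", "pos_As", "strand_As"))
  q[, site_id := .I]
  data.table::setcolorder(q, c("site_id", "context"))
  q[]
}

## coordinate columns of a quartet map used by a panel, per subgenome copy.
## coords: "A" (diploid A), "D" (diploid D), "tet" (allotetraploid genome,
## As+Ds chromosomes) or "AD" (hybrid mapped to the combined diploid genome).
map_coords <- function(site_map, coords, copy = c("As", "Ds")) {
  copy <- match.arg(copy)
  sel <- switch(coords,
    A = "A", D = "D",
    tet = copy,
    AD = if (copy == "As") "A" else "D",
    stop_polymeth("unknown panel coordinate system '%s'", coords))
  data.table::data.table(
    site_id = site_map$site_id,
    chrom = site_map[[paste0("chrom_", sel)]],
    pos = site_map[[paste0("pos_", sel)]],
    strand = site_map[[paste0("strand_", sel)]],
    context = site_map$context)
}

#' Confirm conserved cytosines by read coverage and guanine support
#'
#' Retains map entries where, in every listed species panel and every
#' replicate, each mapped coordinate of the site is covered by at least
#' `min_reads` reads, and -- when the panel carries guanine-confirmation
#' counts (`g_` columns) -- the complementary-strand guanine support also
#' reaches `min_reads`.
#'
#' @param site_map quartet site map ([combine_quartet_map()]).
#' @param panels named list of [methylome_panel()] objects.
#' @param coords named character vector mapping each panel name to its
#'   coordinate system ("A", "D", "tet" or "AD").
#' @param min_reads minimum reads (default 3).
#' @return the filtered site map (same columns).
#' @export
confirm_conserved_cytosines <- function(site_map, panels, coords, min_reads = 3L) {
  missing_sp <- setdiff(names(panels), names(coords))
  assert_that(length(missing_sp) == 0,
              "species missing from coords: %s", paste(missing_sp, collapse = ", "))
  ok <- rep(TRUE, nrow(site_map))
  for (sp in names(panels)) {
    panel <- panels[[sp]]
    copies <- if (coords[[sp]] %in% c("A", "D")) "As" else c("As", "Ds")
    ## diploids have one coordinate per site; tetraploid/hybrid panels carry
    ## both subgenome copies, each of which must pass
    for (cp in copies) {
      mc <- map_coords(site_map, coords[[sp]], cp)
      ok <- ok & site_covered(panel, mc, min_reads)
    }
  }
  site_map[ok]
}

## logical vector over map rows: TRUE iff covered (and g-confirmed when
## available) at >= min_reads in every replicate
site_covered <- function(panel, mc, min_reads) {
  reps <- panel_replicates(panel)
  has_g <- all(paste0("g_", reps) %in% names(panel))
  idx <- panel[mc, on = c("chrom", "pos", "strand"), which = TRUE]
  ok <- !is.na(idx)
  if (!any(ok)) return(ok)
  sub <- panel[idx[ok]]
  good <- rep(TRUE, nrow(sub))
  for (r in reps) {
    good <- good & (sub[[paste0("c_", r)]] + sub[[paste0("t_", r)]]) >= min_reads
    if (has_g) good <- good & sub[[paste0("g_", r)]] >= min_reads
  }
  ok[ok] <- good
  ok
}
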