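#' Read a CX-style per-cytosine bisulfite count report
#'
#' Tab-separated columns: chrom, 1-based position, strand (+/-), methylated
#' read count, unmethylated read count, context (CG/CHG/CHH), and optionally
#' a seventh column with complementary-strand guanine-confirmation reads.
#' Positions are converted to 0-based on read.  When `genome` is supplied,
#' the context of every site is cross-checked against the sequence.
#'
#' @param path file path.
#' @param genome optional named `DNAStringSet` (or named character vector of
#'   chromosome sequences) used to validate contexts.
#' @return data.table with columns chrom, pos (0-based), strand, context,
#'   c, t and (if present in the file) g.
#' @export
read_cx_report <- function(path, genome = NULL) {
  empty <- data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), context = character(),
                                  c = integer(), t = integer())
  if (file.exists(path) && file.size(path) == 0) return(empty)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = FALSE),
    error = function(e) stop_polymeth("malformed CX report '%s': %s",
                                      path, conditionMessage(e))
  )
  if (nrow(dt) == 0) return(empty)
  assert_that(ncol(dt) %in% c(6L, 7L),
              "CX report '%s' must have 6 or 7 columns, found %d", path, ncol(dt))
  nm <- c("chrom", "pos", "strand", "c", "t", "context")
  if (ncol(dt) == 7L) nm <- c(nm, "g")
  data.table::setnames(dt, nm)
  bad <- which(!dt$strand %in% c("+", "-") | is.na(dt$pos) | dt$pos < 1 |
                 is.na(dt$c) | dt$c < 0 | is.na(dt$t) | dt$t < 0 |
                 !dt$context %in% VALID_CONTEXTS)
  if (length(bad) > 0) {
    stop_polymeth("malformed CX report row at line %d of '%s'", bad[1], path)
  }
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos) - 1L]  # to 0-based
  if (!is.null(genome)) {
    expect <- derive_context(genome, dt$chrom, dt$pos, dt$strand)
    mism <- which(expect != dt$context)
    if (length(mism) > 0) {
      i <- mism[1]
      stop_polymeth(
        "context mismatch vs genome at %s:%d(%s): file says %s, genome says %s (%d sites total)",
        dt$chrom[i], dt$pos[i] + 1L, dt$strand[i], dt$context[i], expect[i],
        length(mism))
    }
  }
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "context", "c", "t"))
  dt[]
}

#' Write a CX-style report (1-based positions restored)
#'
#' @param sites data.table with chrom, pos (0-based), strand, context, c, t
#'   and optionally g.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sites, path) {
  dt <- data.table::as.data.table(sites)
  out <- dt[, .(chrom, pos = pos + 1L, strand, c, t, context)]
  if ("g" %in% names(dt)) out[, g := dt$g]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write / read DMR records as BED6+
#'
#' BED columns: chrom, start, end (0-based half-open), name (window id),
#' score (round(1000*|delta|)), strand ("."), then delta, p_value, context,
#' direction.  A single `#`-prefixed header line names the columns, so an
#' empty record set round-trips as a header-only file.  Unsorted input is
#' sorted with a warning.
#'
#' @param dmrs data.table of DMR records (chrom, start, end, delta, p_value,
#'   context, direction and optionally win_id).
#' @param path output file.
#' @return `write_dmr_bed()` returns `path` invisibly; `read_dmr_bed()`
#'   returns the records.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dt <- data.table::as.data.table(dmrs)
  if (nrow(dt) > 0) {
    o <- order(dt$chrom, dt$start)
    if (!identical(o, seq_len(nrow(dt)))) {
      warning("DMR records were not sorted by (chrom, start); sorting")
      dt <- dt[o]
    }
  }
  header <- "#chrom\tstart\tend\tname\tscore\tstrand\tdelta\tp_value\tcontext\tdirection"
  lines <- header
  if (nrow(dt) > 0) {
    name <- if ("win_id" %in% names(dt)) dt$win_id else paste0(dt$chrom, ":", dt$start)
    body <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.17g\t%.17g\t%s\t%s",
                    dt$chrom, as.integer(dt$start), as.integer(dt$end), name,
                    as.integer(round(1000 * abs(dt$delta))),
                    dt$delta, dt$p_value, dt$context, dt$direction)
    lines <- c(header, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dmr_bed
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      win_id = character(), delta = numeric(), p_value = numeric(),
      context = character(), direction = character()))
  }
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t")
  data.table::setnames(dt, c("chrom", "start", "end", "win_id", "score",
                             "strand", "delta", "p_value", "context", "direction"))
  dt[, c("score", "strand") := NULL]
  dt[]
}

#' Read / write MAF-like pairwise alignment blocks
#'
#' Each block is an `a score=<num>` line followed by two `s` rows (source
#' then target): `s <chrom> <start> <size> <strand> <chrom_size> <text>`.
#' Starts are 0-based forward-strand coordinates; a `-` strand on the target
#' row means the target positions pair with the source in descending order.
#' Gapped columns (a `-` in either row) produce no position pair.
#'
#' @param path file path.
#' @return list of blocks; each block has `score`, `src` and `tgt`
#'   (chrom/start/end/strand) and an integer matrix `pairs` with columns
#'   `src_pos`, `tgt_pos` (0-based).
#' @export
read_alignment_blocks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  a_idx <- which(startsWith(lines, "a"))
  blocks <- vector("list", length(a_idx))
  for (i in seq_along(a_idx)) {
    j <- a_idx[i]
    assert_that(j + 2 <= length(lines) &&
                  startsWith(lines[j + 1], "s") && startsWith(lines[j + 2], "s"),
                "alignment block %d lacks two 's' rows", i)
    score <- as.numeric(sub(".*score=([-0-9.eE+]+).*", "\\1", lines[j]))
    assert_that(is.finite(score), "alignment block %d has no numeric score", i)
    src <- parse_s_row(lines[j + 1], i)
    tgt <- parse_s_row(lines[j + 2], i)
    assert_that(nchar(src$text) == nchar(tgt$text),
                "alignment block %d rows have unequal aligned length", i)
    blocks[[i]] <- make_block(score, src, tgt)
  }
  blocks
}

parse_s_row <- function(line, block_i) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  assert_that(length(f) == 7, "malformed 's' row in alignment block %d", block_i)
  list(chrom = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
       strand = f[5], chrom_size = as.integer(f[6]), text = f[7])
}

make_block <- function(score, src, tgt) {
  sch <- strsplit(src$text, "")[[1]]
  tch <- strsplit(tgt$text, "")[[1]]
  keep <- sch != "-" & tch != "-"
  src_off <- cumsum(sch != "-") - 1L  # offset within ungapped source
  tgt_off <- cumsum(tch != "-") - 1L
  src_pos <- src$start + src_off[keep]
  tgt_pos <- if (tgt$strand == "-") {
    tgt$start + tgt$size - 1L - tgt_off[keep]
  } else {
    tgt$start + tgt_off[keep]
  }
  list(score = score,
       src = list(chrom = src$chrom, start = src$start,
                  end = src$start + src$size, strand = src$strand),
       tgt = list(chrom = tgt$chrom, start = tgt$start,
                  end = tgt$start + tgt$size, strand = tgt$strand),
       pairs = cbind(src_pos = as.integer(src_pos), tgt_pos = as.integer(tgt_pos)))
}

#' @rdname read_alignment_blocks
#' @param blocks list of blocks (as returned by [read_alignment_blocks()],
#'   or with `src_text`/`tgt_text` character fields for writing).
#' @export
write_alignment_blocks <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in blocks) {
    src_text <- b$src_text %||% strrep("N", b$src$end - b$src$start)
    tgt_text <- b$tgt_text %||% src_text
    writeLines(sprintf("a score=%.10g", b$score), con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$src$chrom, b$src$start,
                       b$src$end - b$src$start, b$src$strand,
                       b$src$chrom_size %||% b$src$end, src_text), con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$tgt$chrom, b$tgt$start,
                       b$tgt$end - b$tgt$start, b$tgt$strand,
                       b$tgt$chrom_size %||% b$tgt$end, tgt_text), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read a phylogenetic tree in newick format
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; bootstrap
#' supports stored in `tree$node.label` are serialized as internal node
#' labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Read / write genomic features (genes, TEs, promoters) as GFF3
#'
#' Features are handled internally as a data.table with 0-based half-open
#' coordinates and a `kind` column (gene, TE_classI, TE_classII, promoter);
#' on disk they are standard 1-based GFF3 via rtracklayer.
#'
#' @param path GFF3 file.
#' @return data.table with chrom, start, end, strand, kind, id.
#' @export
read_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
    kind = as.character(gr$type),
    id = as.character(gr$ID %||% seq_along(gr))
  )
}

#' @rdname read_features
#' @param features feature data.table.
#' @export
write_features <- function(features, path) {
  dt <- data.table::as.data.table(features)
  assert_that(all(dt$start < dt$end), "features must satisfy start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = dt$strand
  )
  gr$type <- dt$kind
  gr$ID <- dt$id
  gr$source <- "polymeth"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write / read genomes as FASTA
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param path FASTA file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write / read a conserved-site map as TSV
#'
#' @param site_map site-map data.table (see [build_site_map()]).
#' @param path file path.
#' @export
write_site_map <- function(site_map, path) {
  data.table::fwrite(site_map, path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_map
#' @export
read_site_map <- function(path) {
  data.table::fread(path, sep = "\t")
}
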