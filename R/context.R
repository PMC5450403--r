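## cytosine context from genome sequence
##
## For a cytosine on the + strand at 0-based position p: CG if base p+1 is G;
## CHG if p+1 != G and p+2 is G; CHH otherwise.  On the - strand (a G on the
## + strand at p), the next bases along the - strand are the complements of
## + strand bases p-1, p-2.  Sites whose context window runs off the
## chromosome end are labelled NA.

genome_as_char <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    unlist(genome)
  }
}

context_from_neighbors <- function(n1, n2) {
  ## CG needs only the next base; CHG/CHH need both
  ctx <- rep(NA_character_, length(n1))
  ctx[!is.na(n1) & n1 == "G"] <- "CG"
  known <- !is.na(n1) & n1 != "G" & !is.na(n2)
  ctx[known & n2 == "G"] <- "CHG"
  ctx[known & n2 != "G"] <- "CHH"
  ctx
}

#' Derive cytosine context from a genome sequence
#'
#' @param genome named `DNAStringSet` or named character vector of
#'   chromosome sequences.
#' @param chrom,pos,strand site coordinates (0-based positions).
#' @return character vector of contexts (CG/CHG/CHH), `NA` where the
#'   position is not a cytosine on the given strand or the context window
#'   exceeds the chromosome.
#' @export
derive_context <- function(genome, chrom, pos, strand) {
  seqs <- genome_as_char(genome)
  assert_that(all(chrom %in% names(seqs)),
              "unknown chromosome(s): %s",
              paste(setdiff(unique(chrom), names(seqs)), collapse = ", "))
  ctx <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    s <- seqs[[ch]]
    len <- nchar(s)
    idx <- which(chrom == ch)
    p <- pos[idx]
    st <- strand[idx]
    base <- substring(s, p + 1L, p + 1L)
    plus <- st == "+" & base == "C"
    minus <- st == "-" & base == "G"
    n1 <- rep(NA_character_, length(p))
    n2 <- rep(NA_character_, length(p))
    if (any(plus)) {
      n1[plus] <- substring(s, p[plus] + 2L, p[plus] + 2L)
      n2[plus] <- substring(s, p[plus] + 3L, p[plus] + 3L)
    }
    if (any(minus)) {
      n1[minus] <- comp_base(substring(s, p[minus], p[minus]))
      n2[minus] <- comp_base(substring(s, p[minus] - 1L, p[minus] - 1L))
    }
    n1[n1 == ""] <- NA_character_
    n2[n2 == ""] <- NA_character_
    ctx[idx[plus | minus]] <- context_from_neighbors(n1[plus | minus],
                                                     n2[plus | minus])
  }
  ctx
}

comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Enumerate all context-resolvable cytosine sites of a genome
#'
#' Scans both strands and returns every cytosine whose CG/CHG/CHH context is
#' determined by the sequence (sites within two bases of a chromosome end
#' are skipped).
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @return data.table with chrom, pos (0-based), strand, context.
#' @export
cytosine_sites <- function(genome) {
  seqs <- genome_as_char(genome)
  out <- data.table::rbindlist(lapply(names(seqs), function(ch) {
    v <- strsplit(seqs[[ch]], "")[[1]]
    len <- length(v)
    if (len < 3) return(NULL)
    plus <- which(v == "C")
    plus <- plus[plus <= len - 1L]
    minus <- which(v == "G")
    minus <- minus[minus >= 2L]
    at <- function(i) {  # NA-safe indexing beyond the chromosome ends
      out <- rep(NA_character_, length(i))
      ok <- i >= 1L & i <= len
      out[ok] <- v[i[ok]]
      out
    }
    dt_p <- if (length(plus)) data.table::data.table(
      chrom = ch, pos = plus - 1L, strand = "+",
      context = context_from_neighbors(at(plus + 1L), at(plus + 2L))) else NULL
    dt_m <- if (length(minus)) data.table::data.table(
      chrom = ch, pos = minus - 1L, strand = "-",
      context = context_from_neighbors(comp_base(at(minus - 1L)),
                                       comp_base(at(minus - 2L)))) else NULL
    data.table::rbindlist(list(dt_p, dt_m))
  }))
  out <- out[!is.na(context)]
  data.table::setkeyv(out, c("chrom", "pos", "strand"))
  out[]
}
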