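## Nei-Gojobori (1986) synonymous substitution rate with Jukes-Cantor
## correction.
##
## Conventions: single-nucleotide changes that would create a stop codon
## count as nonsynonymous in the site census; mutation pathways passing
## through a stop codon are excluded from the pathway average (when every
## pathway is blocked, all pathways are used with stop steps counted as
## nonsynonymous).

NUCS <- c("A", "C", "G", "T")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

translate_codon <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) tab <<- codon_table()
    tab[[codon]]
  }
})

is_stop <- function(codon) identical(translate_codon(codon), "*")

.ng86_cache <- new.env(parent = emptyenv())

## synonymous site count of one codon: per position, the fraction of the
## three possible changes that preserve the amino acid
ng86_codon_sites <- function(codon) {
  key <- paste0("S_", codon)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  .ng86_cache[[key]] <- ng86_codon_sites_impl(codon)
}

ng86_codon_sites_impl <- function(codon) {
  assert_that(!is_stop(codon), "stop codon '%s' has no site count", codon)
  aa <- translate_codon(codon)
  s <- 0
  for (p in 1:3) {
    for (nt in setdiff(NUCS, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (!is_stop(mut) && translate_codon(mut) == aa) s <- s + 1 / 3
    }
  }
  s
}

## average synonymous/nonsynonymous differences between two codons over all
## mutational pathways (permutations of the differing positions)
ng86_codon_diffs <- function(c1, c2) {
  key <- paste0("D_", c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  .ng86_cache[[key]] <- ng86_codon_diffs_impl(c1, c2)
}

ng86_codon_diffs_impl <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(diff_pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- permutations_of(diff_pos)
  path_sd <- numeric(0); path_nd <- numeric(0)
  blocked_sd <- numeric(0); blocked_nd <- numeric(0)
  for (ord in perms) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop(nxt) && nxt != c2) blocked <- TRUE
      if (is_stop(cur) || is_stop(nxt)) {
        nd <- nd + 1  # steps touching a stop are nonsynonymous by convention
      } else if (translate_codon(cur) == translate_codon(nxt)) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    if (blocked) {
      blocked_sd <- c(blocked_sd, sd); blocked_nd <- c(blocked_nd, nd)
    } else {
      path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
    }
  }
  if (length(path_sd) == 0) {
    path_sd <- blocked_sd; path_nd <- blocked_nd
  }
  c(sd = mean(path_sd), nd = mean(path_nd))
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  assert_that(nchar(seq) %% 3 == 0,
              "coding sequence length %d is not a multiple of 3", nchar(seq))
  assert_that(!grepl("-", seq), "coding sequences must be gap-free")
  n <- nchar(seq) / 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Synonymous substitution rate (Ks) by the Nei-Gojobori 1986 method
#'
#' Counts synonymous sites and differences by codon-pathway averaging, then
#' applies the Jukes-Cantor correction Ks = -3/4 * ln(1 - 4/3 * ps) with
#' ps = Sd/S.  The two sequences must form an equal-length, gap-free codon
#' alignment without internal stop codons.  A terminal stop codon pair is
#' trimmed.  Saturated divergence (ps >= 3/4) returns `NA` with a warning.
#'
#' @param cds_a,cds_b aligned coding sequences (character strings).
#' @return list with `Ks`, `ps`, `S` (synonymous sites, averaged over the
#'   two sequences) and `Sd` (synonymous differences).
#' @export
ks_ng86 <- function(cds_a, cds_b) {
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  assert_that(length(ca) == length(cb),
              "aligned coding sequences differ in length (%d vs %d codons)",
              length(ca), length(cb))
  n <- length(ca)
  if (n > 1 && is_stop(ca[n]) && is_stop(cb[n])) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
  }
  for (i in seq_len(n)) {
    assert_that(!is_stop(ca[i]) && !is_stop(cb[i]),
                "internal stop codon at codon %d", i)
  }
  S_a <- sum(vapply(ca, ng86_codon_sites, numeric(1)))
  S_b <- sum(vapply(cb, ng86_codon_sites, numeric(1)))
  S <- (S_a + S_b) / 2
  d <- vapply(seq_len(n), function(i) ng86_codon_diffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d["sd", ])
  ps <- if (S > 0) Sd / S else 0
  ks <- if (ps >= 3 / 4) {
    warning("synonymous divergence saturated (ps >= 3/4); Ks undefined")
    NA_real_
  } else {
    -3 / 4 * log(1 - 4 / 3 * ps)
  }
  list(Ks = ks, ps = ps, S = S, Sd = Sd)
}
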