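#' Simulate diploid and allotetraploid genomes with planted homology
#'
#' Builds the A and D diploid genomes as alternating diverged tracts
#' (independent sequence) and conserved tracts (>= 2 kb, identical sequence,
#' shared between A and D and copied into the As/Ds subgenomes of the
#' allotetraploid reference).  Ortholog genes are placed inside conserved
#' tracts at corresponding offsets; TE annotations are placed per genome
#' with a higher genic TE fraction in D than in A.  Alignment block sets
#' (A-to-tetraploid, D-to-tetraploid, A-to-D) exactly encode the planted
#' homology, plus low-score/short decoy blocks in diverged regions that the
#' conserved-region filter must reject.  Coding sequences for every
#' ortholog pair are simulated with i.i.d. substitutions at a per-gene
#' gamma-scaled rate.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return a list (class `polymeth_sim_genomes`) with genome sequences,
#'   tract table, per-genome cytosine site tables (with ancestral ids and
#'   genomic classes), gene/TE annotations, alignment block sets, the
#'   ground-truth quartet site map, coding sequences and gene metadata.
#' @export
simulate_genomes <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n_chr <- cfg$n_chromosomes
  L <- cfg$chrom_length
  assert_that(L >= sum(cfg$conserved_tract_len) + sum(cfg$diverged_tract_len),
              "chromosome too short for the requested tract structure")
  chr_ids <- sprintf("%02d", seq_len(n_chr))
  rnd_seq <- function(n) {
    gc <- cfg$gc_content
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }
  tracts <- list(); seq_A <- character(); seq_D <- character()
  tract_id <- 0L
  for (ci in seq_len(n_chr)) {
    pa <- 0L; pd <- 0L
    parts_A <- character(); parts_D <- character()
    repeat {
      div_a <- sample(cfg$diverged_tract_len[1]:cfg$diverged_tract_len[2], 1)
      div_d <- sample(cfg$diverged_tract_len[1]:cfg$diverged_tract_len[2], 1)
      cons <- sample(cfg$conserved_tract_len[1]:cfg$conserved_tract_len[2], 1)
      if (pa + div_a + cons > L || pd + div_d + cons > L) break
      parts_A <- c(parts_A, rnd_seq(div_a))
      parts_D <- c(parts_D, rnd_seq(div_d))
      pa <- pa + div_a; pd <- pd + div_d
      cons_seq <- rnd_seq(cons)
      tract_id <- tract_id + 1L
      tracts[[tract_id]] <- data.table::data.table(
        tract_id = tract_id, chrom_idx = ci,
        start_A = pa, start_D = pd, len = cons)
      parts_A <- c(parts_A, cons_seq)
      parts_D <- c(parts_D, cons_seq)
      pa <- pa + cons; pd <- pd + cons
    }
    parts_A <- c(parts_A, rnd_seq(L - pa))
    parts_D <- c(parts_D, rnd_seq(L - pd))
    seq_A[paste0("A", chr_ids[ci])] <- paste(parts_A, collapse = "")
    seq_D[paste0("D", chr_ids[ci])] <- paste(parts_D, collapse = "")
  }
  tracts <- data.table::rbindlist(tracts)
  tracts[, `:=`(chrom_A = paste0("A", chr_ids[chrom_idx]),
                chrom_D = paste0("D", chr_ids[chrom_idx]),
                chrom_As = paste0("As", chr_ids[chrom_idx]),
                chrom_Ds = paste0("Ds", chr_ids[chrom_idx]))]
  genome_A <- seq_A
  genome_D <- seq_D
  genome_tet <- c(stats::setNames(seq_A, paste0("As", chr_ids)),
                  stats::setNames(seq_D, paste0("Ds", chr_ids)))

  ## ---- ortholog genes in conserved tracts ------------------------------
  gene_tracts <- tracts[len >= cfg$gene_len + 400L]
  genes <- gene_tracts[, .(tract_id, chrom_A, start_A, chrom_D, start_D,
                           chrom_As, chrom_Ds, len)]
  genes[, `:=`(gene_id = sprintf("g%03d", tract_id),
               offset = 200L,
               strand = rep(c("+", "-"), length.out = .N))]
  genes[, `:=`(gstart_A = start_A + offset, gend_A = start_A + offset + cfg$gene_len,
               gstart_D = start_D + offset, gend_D = start_D + offset + cfg$gene_len)]
  gene_meta <- genes[, .(gene_id, tract_id, strand)]
  gene_meta[, bm := stats::runif(.N) < cfg$bm_gene_frac]

  ## ---- TE annotations per genome ---------------------------------------
  place_tes <- function(genome_label) {
    frac_genic <- cfg$te_genic_frac[[genome_label]]
    out <- list()
    for (ci in seq_len(n_chr)) {
      chrom <- paste0(genome_label, chr_ids[ci])
      n_te <- cfg$n_te_per_chrom
      n_genic <- round(n_te * frac_genic)
      g <- genes[get(paste0("chrom_", genome_label)) == chrom]
      k <- 0L
      if (nrow(g) > 0 && n_genic > 0) {
        pick <- sample(nrow(g), n_genic, replace = TRUE)
        gs <- g[[paste0("gstart_", genome_label)]][pick]
        ge <- g[[paste0("gend_", genome_label)]][pick]
        st <- gs + sapply(ge - gs - cfg$te_len, function(m) sample(max(1, m), 1))
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = chrom, start = as.integer(st),
          end = as.integer(pmin(st + cfg$te_len, ge)))
        k <- n_genic
      }
      n_rest <- n_te - k
      gs_all <- genes[get(paste0("chrom_", genome_label)) == chrom,
                      .(s = get(paste0("gstart_", genome_label)),
                        e = get(paste0("gend_", genome_label)))]
      starts <- integer(0); tries <- 0L
      while (length(starts) < n_rest && tries < 50L * n_rest) {
        cand <- sample(L - cfg$te_len, 1)
        mid <- cand + cfg$te_len %/% 2
        if (nrow(gs_all) == 0 || !any(mid >= gs_all$s & mid < gs_all$e)) {
          starts <- c(starts, cand)
        }
        tries <- tries + 1L
      }
      if (length(starts) > 0) {
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = chrom, start = as.integer(starts),
          end = as.integer(starts + cfg$te_len))
      }
    }
    te <- data.table::rbindlist(out)
    te[, `:=`(strand = "+",
              kind = sample(c("TE_classI", "TE_classII"), .N, replace = TRUE),
              id = sprintf("te_%s_%03d", genome_label, seq_len(.N)))]
    te[]
  }
  tes_A <- place_tes("A")
  tes_D <- place_tes("D")

  ## ---- cytosine site tables with classes -------------------------------
  sites_A <- annotate_sites(cytosine_sites(genome_A), tracts, genes, tes_A,
                            gene_meta, "A")
  sites_D <- annotate_sites(cytosine_sites(genome_D), tracts, genes, tes_D,
                            gene_meta, "D")

  ## ---- ground-truth quartet site map -----------------------------------
  ia <- which(!is.na(sites_A$tract_id))
  ca <- sites_A[ia, .(tract_id, offset, strand, context,
                      chrom_A = chrom, pos_A = pos)][, idx_A := ia]
  idd <- which(!is.na(sites_D$tract_id))
  cd <- sites_D[idd, .(tract_id, offset, strand, context,
                       chrom_D = chrom, pos_D = pos)][, idx_D := idd]
  tm <- merge(ca, cd, by = c("tract_id", "offset", "strand", "context"))
  tm <- merge(tm, tracts[, .(tract_id, chrom_As, chrom_Ds)], by = "tract_id")
  tm[, `:=`(pos_As = pos_A, pos_Ds = pos_D,
            strand_A = strand, strand_D = strand,
            strand_As = strand, strand_Ds = strand)]
  data.table::setorderv(tm, c("chrom_As", "pos_As", "strand_As"))
  tm[, site_id := .I]
  truth_map <- tm[, .(site_id, context, chrom_A, pos_A, strand_A,
                      chrom_D, pos_D, strand_D, chrom_As, pos_As, strand_As,
                      chrom_Ds, pos_Ds, strand_Ds, idx_A, idx_D)]

  ## ---- alignment blocks (+ decoys) -------------------------------------
  blocks <- make_block_sets(tracts, genome_A, genome_D, cfg)

  ## ---- coding sequences ------------------------------------------------
  cds <- simulate_cds(gene_meta, cfg)

  structure(list(
    cfg = cfg, chr_ids = chr_ids,
    genome_A = genome_A, genome_D = genome_D, genome_tet = genome_tet,
    tracts = tracts, genes = genes, gene_meta = cds$gene_meta,
    tes_A = tes_A, tes_D = tes_D,
    sites_A = sites_A, sites_D = sites_D,
    truth_map = truth_map, blocks = blocks,
    cds = cds$seqs
  ), class = "polymeth_sim_genomes")
}

## add tract/gene/TE annotation and root class to a site table
annotate_sites <- function(sites, tracts, genes, tes, gene_meta, genome_label) {
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  tr <- tracts[, .(chrom = get(paste0("chrom_", genome_label)),
                   t_start = get(paste0("start_", genome_label)),
                   t_end = get(paste0("start_", genome_label)) + len, tract_id)]
  sites[, `:=`(tract_id = NA_integer_, offset = NA_integer_)]
  ov <- GenomicRanges::findOverlaps(
    gr_sites, GenomicRanges::GRanges(tr$chrom,
                                     IRanges::IRanges(tr$t_start + 1L, tr$t_end)))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  sites$tract_id[qh] <- tr$tract_id[sh]
  sites$offset[qh] <- sites$pos[qh] - tr$t_start[sh]
  gn <- genes[, .(chrom = get(paste0("chrom_", genome_label)),
                  g_start = get(paste0("gstart_", genome_label)),
                  g_end = get(paste0("gend_", genome_label)), gene_id)]
  sites[, gene_id := NA_character_]
  if (nrow(gn) > 0) {
    ov <- GenomicRanges::findOverlaps(
      gr_sites, GenomicRanges::GRanges(gn$chrom,
                                       IRanges::IRanges(gn$g_start + 1L, gn$g_end)))
    sites$gene_id[S4Vectors::queryHits(ov)] <-
      gn$gene_id[S4Vectors::subjectHits(ov)]
  }
  sites[, in_te := FALSE]
  if (nrow(tes) > 0) {
    ov <- GenomicRanges::findOverlaps(
      gr_sites, GenomicRanges::GRanges(tes$chrom,
                                       IRanges::IRanges(tes$start + 1L, tes$end)))
    sites$in_te[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  bm_ids <- gene_meta[bm == TRUE, gene_id]
  sites[, class := data.table::fcase(
    in_te & !is.na(gene_id), "te_genic",
    in_te, "te",
    !is.na(gene_id) & gene_id %in% bm_ids, "gene_bm",
    !is.na(gene_id), "gene_um",
    default = "bg")]
  sites[]
}

make_block_sets <- function(tracts, genome_A, genome_D, cfg) {
  tract_block <- function(src_chrom, src_start, tgt_chrom, tgt_start, len,
                          seqtext, score = NULL) {
    list(score = score %||% round(1.5 * len),
         src = list(chrom = src_chrom, start = src_start,
                    end = src_start + len, strand = "+",
                    chrom_size = cfg$chrom_length),
         tgt = list(chrom = tgt_chrom, start = tgt_start,
                    end = tgt_start + len, strand = "+",
                    chrom_size = cfg$chrom_length),
         src_text = seqtext, tgt_text = seqtext,
         pairs = cbind(src_pos = src_start + 0:(len - 1),
                       tgt_pos = tgt_start + 0:(len - 1)))
  }
  a_tet <- list(); d_tet <- list(); a_d <- list()
  for (i in seq_len(nrow(tracts))) {
    t <- tracts[i]
    seqtext <- substring(genome_A[[t$chrom_A]], t$start_A + 1L, t$start_A + t$len)
    a_tet[[i]] <- tract_block(t$chrom_A, t$start_A, t$chrom_As, t$start_A,
                              t$len, seqtext)
    d_tet[[i]] <- tract_block(t$chrom_D, t$start_D, t$chrom_Ds, t$start_D,
                              t$len, seqtext)
    a_d[[i]] <- tract_block(t$chrom_A, t$start_A, t$chrom_D, t$start_D,
                            t$len, seqtext)
  }
  ## decoys: short-but-strong and long-but-weak alignments in diverged
  ## regions; the conserved-region filter must drop both
  add_decoys <- function(set, src_genome, src_prefix, tgt_prefix) {
    for (ci in seq_along(src_genome)) {
      src_chrom <- names(src_genome)[ci]
      tgt_chrom <- sub(paste0("^", src_prefix), tgt_prefix, src_chrom)
      s1 <- substring(src_genome[[ci]], 1, 800)
      set[[length(set) + 1L]] <- list(
        score = 2500, src = list(chrom = src_chrom, start = 0L, end = 800L,
                                 strand = "+", chrom_size = cfg$chrom_length),
        tgt = list(chrom = tgt_chrom, start = 0L, end = 800L, strand = "+",
                   chrom_size = cfg$chrom_length),
        src_text = s1, tgt_text = s1,
        pairs = cbind(src_pos = 0:799, tgt_pos = 0:799))
      s2 <- substring(src_genome[[ci]], 101, 2600)
      set[[length(set) + 1L]] <- list(
        score = 1200, src = list(chrom = src_chrom, start = 100L, end = 2600L,
                                 strand = "+", chrom_size = cfg$chrom_length),
        tgt = list(chrom = tgt_chrom, start = 100L, end = 2600L, strand = "+",
                   chrom_size = cfg$chrom_length),
        src_text = s2, tgt_text = s2,
        pairs = cbind(src_pos = 100:2599, tgt_pos = 100:2599))
    }
    set
  }
  a_tet <- add_decoys(a_tet, genome_A, "A", "As")
  d_tet <- add_decoys(d_tet, genome_D, "D", "Ds")
  list(A_tet = a_tet, D_tet = d_tet, A_D = a_d)
}

SENSE_CODONS <- NULL

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

simulate_cds <- function(gene_meta, cfg) {
  codons <- sense_codons()
  gene_meta <- data.table::copy(gene_meta)
  gene_meta[, ks_gamma := stats::rgamma(.N, shape = cfg$ks_shape,
                                        rate = cfg$ks_shape)]
  seqs <- character(0)
  for (i in seq_len(nrow(gene_meta))) {
    cd <- c("ATG", sample(codons, cfg$cds_codons - 1L, replace = TRUE))
    a_seq <- paste(cd, collapse = "")
    rate <- cfg$ks_rate * gene_meta$ks_gamma[i]
    b <- strsplit(a_seq, "")[[1]]
    nmut <- stats::rbinom(1, length(b), rate)
    if (nmut > 0) {
      tries <- 0L
      while (nmut > 0 && tries < 20L * nmut) {
        p <- sample(length(b), 1)
        old <- b[p]
        b[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        codon_i <- (p - 1) %/% 3 + 1
        codon <- paste(b[(3 * codon_i - 2):(3 * codon_i)], collapse = "")
        if (Biostrings::GENETIC_CODE[[codon]] == "*") {
          b[p] <- old  # reject mutations creating stops
        } else {
          nmut <- nmut - 1L
        }
        tries <- tries + 1L
      }
    }
    seqs[paste0(gene_meta$gene_id[i], "_A")] <- a_seq
    seqs[paste0(gene_meta$gene_id[i], "_D")] <- paste(b, collapse = "")
  }
  list(seqs = seqs, gene_meta = gene_meta)
}
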