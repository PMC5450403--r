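mk_block <- function(score, src_chrom, src_start, len, tgt_chrom, tgt_start,
                     strand = "+") {
  list(score = score,
       src = list(chrom = src_chrom, start = src_start, end = src_start + len,
                  strand = "+"),
       tgt = list(chrom = tgt_chrom, start = tgt_start, end = tgt_start + len,
                  strand = strand),
       pairs = cbind(src_pos = src_start + 0:(len - 1),
                     tgt_pos = if (strand == "-")
                       (tgt_start + len - 1):tgt_start else
                         tgt_start + 0:(len - 1)))
}

test_that("conserved-region filter enforces score, uniqueness and length", {
  b_keep <- mk_block(2500, "A01", 1000, 3000, "As01", 1000)
  expect_length(select_conserved_regions(list(b_keep)), 1)
  ## final score and length rules
  b_short <- mk_block(3000, "A01", 9000, 1500, "As01", 9000)
  b_weak <- mk_block(1500, "A01", 20000, 3000, "As01", 20000)
  b_first <- mk_block(400, "A01", 30000, 3000, "As01", 30000)
  kept <- select_conserved_regions(list(b_keep, b_short, b_weak, b_first))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$score, 2500)
  ## overlapping blocks: higher score wins
  b_lo <- mk_block(2200, "A01", 2000, 3000, "As02", 5000)
  kept <- select_conserved_regions(list(b_lo, b_keep))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$score, 2500)
  ## target-side overlap also disqualifies
  b_tgt <- mk_block(2200, "A02", 0, 3000, "As01", 2000)
  kept <- select_conserved_regions(list(b_keep, b_tgt))
  expect_length(kept, 1)
  ## blocks without scores error
  expect_error(select_conserved_regions(list(list(src = 1))), "without scores")
})

test_that("site map keeps same-context cytosines and honours substitutions", {
  ##            0123456789
  seq_src <- "AACGTACGTT"
  seq_tgt_same <- seq_src
  seq_tgt_sub <- "AATGTACGTT"   # C->T at pos 2
  seq_tgt_ctx <- "AACTTACGTT"   # G->T at 3: src CG site becomes CHH-ish
  blocks <- list(mk_block(5000, "s", 0, 10, "t", 0))
  m_same <- build_site_map(blocks, list(s = c(s = seq_src), t = c(t = seq_tgt_same)),
                           "s", "t")
  ## 2 CG dinucleotides -> 4 stranded CG records, plus CHH sites
  expect_equal(nrow(m_same[context == "CG"]), 4)
  m_sub <- build_site_map(blocks, list(s = c(s = seq_src), t = c(t = seq_tgt_sub)),
                          "s", "t")
  expect_false(any(m_sub$pos_s == 2))
  m_ctx <- build_site_map(blocks, list(s = c(s = seq_src), t = c(t = seq_tgt_ctx)),
                          "s", "t")
  ## the CG at src pos 2 is no longer CG in the target -> excluded
  expect_false(any(m_ctx[context == "CG"]$pos_s == 2))
  expect_error(
    build_site_map(list(mk_block(5000, "zz", 0, 10, "t", 0)),
                   list(s = c(s = seq_src), t = c(t = seq_tgt_same)), "s", "t"),
    "unknown chromosome")
})

test_that("reverse-oriented blocks map strands and contexts correctly", {
  ## target is the reverse complement of the source; a + strand source
  ## cytosine pairs with a - strand target cytosine of identical context
  src <- "AACGTT"
  tgt <- "AACGTT"  # revcomp of AACGTT is AACGTT (palindrome)
  blocks <- list(mk_block(5000, "s", 0, 6, "t", 0, strand = "-"))
  m <- build_site_map(blocks, list(s = c(s = src), t = c(t = tgt)), "s", "t")
  expect_true(nrow(m) > 0)
  plus_rows <- m[strand_s == "+"]
  expect_true(all(plus_rows$strand_t == "-"))
  ## src pos 2 (C, + strand, CG) maps to tgt pos 3 (G on +, i.e. C on -)
  expect_true(any(plus_rows$pos_s == 2 & plus_rows$pos_t == 3))
})

test_that("coverage and guanine confirmation filter conserved sites", {
  sim <- get_tiny_sim()
  qmap <- sim$truth$site_map
  coords <- c(A = "A", D = "D")
  panels <- sim$panels[c("A", "D")]
  kept3 <- confirm_conserved_cytosines(qmap, panels, coords, 3L)
  kept5 <- confirm_conserved_cytosines(qmap, panels, coords, 5L)
  kept8 <- confirm_conserved_cytosines(qmap, panels, coords, 8L)
  expect_true(nrow(kept3) > 0)
  ## retained set shrinks monotonically with min_reads
  expect_true(nrow(kept5) <= nrow(kept3))
  expect_true(nrow(kept8) <= nrow(kept5))
  expect_error(
    confirm_conserved_cytosines(qmap, sim$panels["wGh"], coords, 3L),
    "missing from coords")
})

test_that("confirmation matches a brute-force oracle on a small panel", {
  sim <- get_tiny_sim()
  qmap <- sim$truth$site_map[1:400]
  panels <- sim$panels[c("A", "wGh")]
  coords <- c(A = "A", wGh = "tet")
  kept <- confirm_conserved_cytosines(qmap, panels, coords, 3L)
  ## oracle: per site, look up every mapped coordinate by hand
  lookup <- function(panel, chrom, pos, strand) {
    row <- panel[list(chrom, pos, strand), on = c("chrom", "pos", "strand")]
    if (nrow(row) == 0 || is.na(row$c_r1[1])) return(FALSE)
    all(row$c_r1 + row$t_r1 >= 3, row$c_r2 + row$t_r2 >= 3,
        row$g_r1 >= 3, row$g_r2 >= 3)
  }
  ok <- vapply(seq_len(nrow(qmap)), function(i) {
    r <- qmap[i]
    lookup(panels$A, r$chrom_A, r$pos_A, r$strand_A) &&
      lookup(panels$wGh, r$chrom_As, r$pos_As, r$strand_As) &&
      lookup(panels$wGh, r$chrom_Ds, r$pos_Ds, r$strand_Ds)
  }, logical(1))
  expect_equal(kept$site_id, qmap$site_id[ok])
})
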