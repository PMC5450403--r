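test_that("Ks is zero for identical sequences and errors on bad input", {
  r <- ks_ng86("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r$Ks, 0)
  expect_equal(r$Sd, 0)
  expect_error(ks_ng86("ATGG", "ATGG"), "multiple of 3")
  expect_error(ks_ng86("ATGTAAAAA", "ATGTAAAAA"), "internal stop")
  expect_error(ks_ng86("ATG-CTAAA", "ATGGCTAAA"), "gap-free")
})

test_that("single synonymous difference matches hand enumeration (TTT/TTC)", {
  ## Phe/Phe: 1 synonymous difference; S(TTT) = S(TTC) = 1/3
  ## ps = 1/(1/3) = 3 >= 3/4: saturated
  expect_warning(r <- ks_ng86("TTT", "TTC"), "saturated")
  expect_equal(r$Sd, 1)
  expect_equal(r$S, 1 / 3)
  expect_true(is.na(r$Ks))
  ## embedded in a longer identical sequence the correction is finite
  a <- paste0("ATGGCTGCTGCTGCT", "TTT")
  b <- paste0("ATGGCTGCTGCTGCT", "TTC")
  r2 <- suppressWarnings(ks_ng86(a, b))
  expect_equal(r2$Sd, 1)
  expect_true(is.finite(r2$Ks) && r2$Ks > 0)
})

test_that("codon site counts and pathway diffs match the oracle on random pairs", {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  set.seed(8)
  pick <- cbind(sample(sense, 40, TRUE), sample(sense, 40, TRUE))
  for (i in seq_len(nrow(pick))) {
    a <- pick[i, 1]; b <- pick[i, 2]
    got <- suppressWarnings(ks_ng86(a, b))
    oracle <- oracle_ng86_pair(a, b)
    expect_equal(got$S, oracle$S, tolerance = 1e-12,
                 label = paste(a, b, "S"))
    expect_equal(got$Sd, oracle$Sd, tolerance = 1e-12,
                 label = paste(a, b, "Sd"))
  }
})

test_that("Ks never decreases when more substitutions are added", {
  set.seed(13)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  base <- c("ATG", sample(setdiff(sense, "ATG"), 29, TRUE))
  a <- paste(base, collapse = "")
  v <- strsplit(a, "")[[1]]
  ks_prev <- 0
  changed_codons <- integer(0)
  for (step in 1:6) {
    repeat {
      p <- sample(4:length(v), 1)
      cod_i <- (p - 1) %/% 3 + 1
      if (cod_i %in% changed_codons) next  # one substitution per codon
      old <- v[p]
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cod <- paste(v[(3 * cod_i - 2):(3 * cod_i)], collapse = "")
      if (Biostrings::GENETIC_CODE[[cod]] != "*") break
      v[p] <- old
    }
    changed_codons <- c(changed_codons, cod_i)
    ks_now <- suppressWarnings(
      ks_ng86(a, paste(v, collapse = ""))$Ks)
    if (is.na(ks_now)) break
    expect_true(ks_now >= ks_prev - 1e-9)
    ks_prev <- ks_now
  }
})
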