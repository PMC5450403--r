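## independent brute-force NG86 oracle: enumerate mutation pathways with a
## different code path from the implementation
oracle_ng86_pair <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  translate <- function(x) unname(gc[x])
  mutate <- function(codon, p, nt) {
    v <- strsplit(codon, "")[[1]]; v[p] <- nt; paste(v, collapse = "")
  }
  syn_sites <- function(codon) {
    aa <- translate(codon)
    total <- 0
    for (p in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
        m <- mutate(codon, p, nt)
        if (gc[m] != "*" && translate(m) == aa) total <- total + 1 / 3
      }
    }
    total
  }
  diffs <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    perms <- if (length(pos) == 1) list(pos) else {
      out <- list()
      rec <- function(prefix, rest) {
        if (length(rest) == 0) out[[length(out) + 1L]] <<- prefix
        for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
      }
      rec(integer(0), pos)
      out
    }
    acc <- matrix(0, 0, 2); acc_blocked <- matrix(0, 0, 2)
    for (ord in perms) {
      cur <- a; sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- mutate(cur, p, substr(b, p, p))
        if (gc[nxt] == "*" && nxt != b) blocked <- TRUE
        if (gc[cur] == "*" || gc[nxt] == "*") nd <- nd + 1
        else if (translate(cur) == translate(nxt)) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      if (blocked) acc_blocked <- rbind(acc_blocked, c(sd, nd))
      else acc <- rbind(acc, c(sd, nd))
    }
    if (nrow(acc) == 0) acc <- acc_blocked
    colMeans(acc)
  }
  d <- diffs(c1, c2)
  list(S = (syn_sites(c1) + syn_sites(c2)) / 2, Sd = d[1])
}

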