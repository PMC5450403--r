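## internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_polymeth <- function(fmt, ..., class = "polymeth_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop_polymeth(fmt, ...)
  invisible(TRUE)
}

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

check_context <- function(context) {
  assert_that(all(context %in% VALID_CONTEXTS),
              "unknown context label(s): %s",
              paste(setdiff(unique(context), VALID_CONTEXTS), collapse = ", "))
  context
}

## deterministic child seeds derived from one master seed; kept < 2^31
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(index) * 12347) %% 2147483647)
}

## 100-bp (by default) tiles over chromosomes; 0-based half-open
tile_windows <- function(chrom_lengths, width = 100L) {
  assert_that(width >= 1, "window width must be >= 1")
  wins <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, max(0L, len - 1L), by = width)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + width, len))
  }))
  wins[, win_id := paste0(chrom, ":", start)]
  wins[]
}

## assign 0-based positions to tile window ids
window_of <- function(chrom, pos, width = 100L) {
  paste0(chrom, ":", (pos %/% width) * width)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
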