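#' One-way ANOVA for two replicate groups
#'
#' The F test used for DmC, DMR and DEG calling: one-way ANOVA between two
#' groups of replicate measurements with df (1, n - 2).  Degenerate inputs
#' follow the limits of the F statistic: zero within-group variance with
#' unequal group means gives p = 0; all values equal gives F = 0, p = 1.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @return list with `F` and `p`.
#' @examples
#' one_way_anova(c(0.1, 0.2), c(0.7, 0.8))  # F = 72
#' @export
one_way_anova <- function(group_a, group_b) {
  assert_that(length(group_a) >= 2 && length(group_b) >= 2,
              "one_way_anova needs at least 2 values per group (got %d and %d)",
              length(group_a), length(group_b))
  n_a <- length(group_a); n_b <- length(group_b)
  m_a <- mean(group_a); m_b <- mean(group_b)
  grand <- (sum(group_a) + sum(group_b)) / (n_a + n_b)
  ssb <- n_a * (m_a - grand)^2 + n_b * (m_b - grand)^2
  ssw <- sum((group_a - m_a)^2) + sum((group_b - m_b)^2)
  df2 <- n_a + n_b - 2L
  if (ssw <= 0) {
    if (isTRUE(all.equal(m_a, m_b))) return(list(F = 0, p = 1))
    return(list(F = Inf, p = 0))
  }
  f <- (ssb / 1) / (ssw / df2)
  list(F = f, p = stats::pf(f, 1, df2, lower.tail = FALSE))
}

## vectorised version over many sites/windows: two replicates per group.
## Returns data.table columns F and p following the same degenerate rules.
anova_2x2_vec <- function(a1, a2, b1, b2) {
  m_a <- (a1 + a2) / 2
  m_b <- (b1 + b2) / 2
  ssb <- (m_a - m_b)^2  # 2*(m_a-g)^2 + 2*(m_b-g)^2 with g=(m_a+m_b)/2
  ssw <- (a1 - m_a)^2 + (a2 - m_a)^2 + (b1 - m_b)^2 + (b2 - m_b)^2
  f <- ssb / (ssw / 2)
  p <- stats::pf(f, 1, 2, lower.tail = FALSE)
  zero_w <- ssw <= .Machine$double.eps * 16
  eq_m <- abs(m_a - m_b) <= .Machine$double.eps * 16
  p[zero_w & eq_m] <- 1
  f[zero_w & eq_m] <- 0
  p[zero_w & !eq_m] <- 0
  f[zero_w & !eq_m] <- Inf
  list(F = f, p = p)
}

#' Upper-tail hypergeometric enrichment test
#'
#' P(X >= k) when drawing `n_drawn` items without replacement from a
#' population of `N_total` containing `K_category` category members.
#' Computed in log space via [stats::phyper()].
#'
#' @param k_observed observed category count among the draws.
#' @param n_drawn number of draws.
#' @param K_category category size in the population.
#' @param N_total population size.
#' @param log return the natural log of the p-value (for extreme
#'   enrichments that underflow on the linear scale).
#' @return the upper-tail p-value (or its log).
#' @examples
#' hypergeometric_enrichment(2, 2, 2, 4)  # 1/6
#' @export
hypergeometric_enrichment <- function(k_observed, n_drawn, K_category,
                                      N_total, log = FALSE) {
  assert_that(all(c(k_observed, n_drawn, K_category, N_total) >= 0),
              "hypergeometric counts must be non-negative")
  assert_that(n_drawn <= N_total && K_category <= N_total,
              "inconsistent hypergeometric counts: n or K exceeds N")
  assert_that(k_observed <= min(n_drawn, K_category),
              "inconsistent hypergeometric counts: k > min(n, K)")
  if (k_observed == 0) return(if (log) 0 else 1)
  stats::phyper(k_observed - 1, K_category, N_total - K_category, n_drawn,
                lower.tail = FALSE, log.p = log)
}

#' Two-sided Wilcoxon signed-rank test for paired vectors
#'
#' Exact for <= 25 informative pairs (tied absolute differences handled by
#' midranks, with the exact null distribution built by dynamic
#' programming); normal approximation with continuity correction above
#' that.  Zero differences are dropped (Wilcoxon's convention); if all
#' differences are zero, p = 1.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return the two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  assert_that(length(paired_a) == length(paired_b),
              "paired vectors must have equal length (%d vs %d)",
              length(paired_a), length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (n <= 25) {
    ## doubled midranks stay integral under ties
    r2 <- as.integer(round(2 * rank(abs(d))))
    t_obs <- sum(r2[d > 0])
    total <- sum(r2)
    cnt <- numeric(total + 1)  # cnt[s + 1] = #subsets with doubled-rank sum s
    cnt[1] <- 1
    for (r in r2) {
      cnt <- cnt + c(rep(0, r), cnt[seq_len(total + 1L - r)])
    }
    probs <- cnt / 2^n
    lower <- sum(probs[seq_len(t_obs + 1L)])
    upper <- sum(probs[seq.int(t_obs + 1L, total + 1L)])
    return(min(1, 2 * min(lower, upper)))
  }
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE)$p.value
  )
}

#' Per-site methylation level
#'
#' level = C / (C + T); sites covered by fewer than `min_coverage` reads are
#' excluded (returned as `NA`).
#'
#' @param c_reads,t_reads non-negative read counts (vectors allowed).
#' @param min_coverage minimum total reads (default 3).
#' @return numeric vector of levels with `NA` at excluded sites.
#' @examples
#' site_level(3, 1)         # 0.75
#' site_level(1, 1)         # NA: coverage 2 < 3
#' @export
site_level <- function(c_reads, t_reads, min_coverage = 3L) {
  assert_that(all(c_reads >= 0, na.rm = TRUE) && all(t_reads >= 0, na.rm = TRUE),
              "read counts must be non-negative")
  cov <- c_reads + t_reads
  lev <- ifelse(cov >= min_coverage, c_reads / cov, NA_real_)
  lev
}
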