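test_that("one-way ANOVA matches hand-computed sums of squares and aov", {
  res <- one_way_anova(c(0.1, 0.2), c(0.7, 0.8))
  ## SSB = 0.36, MSW = 0.005 -> F = 72
  expect_equal(res$F, 72)
  expect_equal(res$p, stats::pf(72, 1, 2, lower.tail = FALSE))
  set.seed(42)
  for (i in 1:20) {
    a <- stats::rnorm(sample(2:5, 1)); b <- stats::rnorm(sample(2:5, 1))
    res <- one_way_anova(a, b)
    expect_equal(res$p, aov_p(a, b), tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs follow the F-statistic limits", {
  expect_equal(one_way_anova(c(0.5, 0.5), c(0.5, 0.5)), list(F = 0, p = 1))
  expect_equal(one_way_anova(c(0, 0), c(1, 1))$p, 0)
  expect_error(one_way_anova(0.5, c(0.2, 0.3)), "at least 2")
})

test_that("vectorised 2x2 ANOVA agrees with the scalar version", {
  set.seed(7)
  a1 <- stats::runif(50); a2 <- stats::runif(50)
  b1 <- stats::runif(50); b2 <- stats::runif(50)
  v <- anova_2x2_vec(a1, a2, b1, b2)
  for (i in seq_len(50)) {
    s <- one_way_anova(c(a1[i], a2[i]), c(b1[i], b2[i]))
    expect_equal(v$p[i], s$p, tolerance = 1e-12)
    expect_equal(v$F[i], s$F, tolerance = 1e-8)
  }
})

test_that("hypergeometric upper tail matches enumeration", {
  ## N=4, K=2, n=2: P(X >= 2) = C(2,2)C(2,0)/C(4,2) = 1/6
  expect_equal(hypergeometric_enrichment(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeometric_enrichment(0, 3, 5, 10), 1)
  expect_equal(hypergeometric_enrichment(3, 3, 3, 3), 1)
  ## enumeration oracle over all k for small populations
  for (N in c(6, 9, 12)) {
    for (K in c(2, 4)) {
      for (n in c(3, 5)) {
        for (k in seq_len(min(n, K))) {
          oracle <- sum(vapply(k:min(n, K), function(x) {
            choose(K, x) * choose(N - K, n - x) / choose(N, n)
          }, numeric(1)))
          expect_equal(hypergeometric_enrichment(k, n, K, N), oracle,
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeometric_enrichment(5, 3, 4, 10), "k > min")
})

test_that("Wilcoxon signed-rank handles exact, ties and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  ## all five differences positive: exact two-sided p = 2/32
  expect_equal(wilcoxon_signed_rank(x + 1, x), 2 / 32)
  expect_equal(wilcoxon_signed_rank(x, x), 1)
  ## antisymmetric swap gives the same p
  y <- x + c(2, -1, 3, -2, 4)
  expect_equal(wilcoxon_signed_rank(x, y), wilcoxon_signed_rank(y, x))
})

test_that("exact signed-rank p matches sign-pattern enumeration for n <= 10", {
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    t_obs <- sum(r[d > 0])
    ts <- vapply(0:(2^n - 1), function(m) {
      signs <- as.integer(intToBits(m))[seq_len(n)]
      sum(r[signs == 1])
    }, numeric(1))
    mu <- n * (n + 1) / 4
    min(1, 2 * min(mean(ts >= t_obs), mean(ts <= t_obs)))
  }
  set.seed(1)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    expect_equal(wilcoxon_signed_rank(a, b), enum_p(a - b), tolerance = 1e-10,
                 label = sprintf("case %d", i))
  }
})

test_that("site level is C/(C+T) with a coverage-3 exclusion", {
  expect_equal(site_level(3, 1), 0.75)
  expect_equal(site_level(0, 5), 0)
  expect_true(is.na(site_level(1, 1)))
  expect_equal(site_level(c(3, 1), c(1, 1)), c(0.75, NA))
  expect_error(site_level(-1, 2), "non-negative")
})
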