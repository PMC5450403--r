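test_that("Euclidean distance follows the explicit formula", {
  expect_equal(euclidean_distance(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(euclidean_distance(c(0, 1), c(1, 1)), 1)
  set.seed(2)
  p <- stats::runif(100); q <- stats::runif(100)
  expect_equal(euclidean_distance(p, q), sqrt(sum((p - q)^2)),
               tolerance = 1e-12)
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
  expect_error(euclidean_distance(c(1, NA), c(1, 2)), "missing")
})

test_that("distance matrices are symmetric, homogeneous and permutable", {
  set.seed(3)
  v <- matrix(stats::runif(30), nrow = 5,
              dimnames = list(paste0("s", 1:5), NULL))
  dm <- distance_matrix(v)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), stats::setNames(rep(0, 5), paste0("s", 1:5)))
  expect_equal(distance_matrix(2 * v), 2 * dm, tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(distance_matrix(v[perm, ]), dm[perm, perm])
  expect_error(distance_matrix(v[1:2, ]), "at least 3")
})

test_that("3-taxon NJ reproduces the closed-form pendant lengths", {
  dm <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  lens <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 5 - 6) / 2)
  expect_equal(lens[["B"]], (3 + 6 - 5) / 2)
  expect_equal(lens[["C"]], (5 + 6 - 3) / 2)
})

test_that("NJ recovers additive quartets exactly", {
  ## tree ((A,B),(C,D)) with pendant 1 and internal edge 1
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 2
  dm["C", "D"] <- dm["D", "C"] <- 2
  for (x in c("A", "B")) for (y in c("C", "D")) {
    dm[x, y] <- dm[y, x] <- 3
  }
  tr <- neighbor_joining(dm)
  expect_true("A|B" %in% tree_bipartitions(tr) ||
                "C|D" %in% tree_bipartitions(tr))
  ## brute force over the 3 quartet topologies by least squares
  fits <- vapply(list(c("A", "B"), c("A", "C"), c("A", "D")), function(pair) {
    rest <- setdiff(LETTERS[1:4], pair)
    ## path design for topology (pair),(rest): columns = 4 pendants + internal
    pairs <- t(combn(LETTERS[1:4], 2))
    X <- matrix(0, nrow(pairs), 5)
    for (k in seq_len(nrow(pairs))) {
      X[k, match(pairs[k, ], LETTERS[1:4])] <- 1
      split_cross <- sum(pairs[k, ] %in% pair) == 1
      if (split_cross) X[k, 5] <- 1
    }
    y <- dm[pairs]
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  expect_equal(which.min(fits), 1)  # (A,B)|(C,D) is the best split
})

test_that("NJ is exact on additive matrices from random trees (n <= 6)", {
  set.seed(11)
  for (n in 4:6) {
    for (rep in 1:5) {
      tr0 <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
      tr0 <- ape::unroot(tr0)
      dm <- ape::cophenetic.phylo(tr0)
      dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
      tr <- neighbor_joining(dm)
      expect_equal(phangorn::RF.dist(tr, tr0), 0)
      ## branch lengths: total tree length must match
      expect_equal(sum(tr$edge.length), sum(tr0$edge.length),
                   tolerance = 1e-8)
    }
  }
})

test_that("NJ agrees with the ape reference implementation", {
  set.seed(21)
  for (rep in 1:5) {
    v <- matrix(stats::runif(7 * 40), nrow = 7,
                dimnames = list(paste0("s", 1:7), NULL))
    dm <- distance_matrix(v)
    mine <- neighbor_joining(dm)
    ref <- ape::nj(stats::as.dist(dm))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(ref)), 0)
  }
})

test_that("adding a constant to one leaf's distances stretches its pendant only", {
  tr0 <- ape::unroot(ape::rtree(5, br = function(k) stats::runif(k, 0.5, 2)))
  dm <- ape::cophenetic.phylo(tr0)
  leaf <- rownames(dm)[1]
  dm2 <- dm
  dm2[leaf, ] <- dm2[leaf, ] + 0.7
  dm2[, leaf] <- dm2[, leaf] + 0.7
  dm2[leaf, leaf] <- 0
  t1 <- neighbor_joining(dm)
  t2 <- neighbor_joining(dm2)
  expect_equal(phangorn::RF.dist(t1, t2), 0)
  pend <- function(tr, tip) {
    tr$edge.length[tr$edge[, 2] == which(tr$tip.label == tip)]
  }
  expect_equal(pend(t2, leaf) - pend(t1, leaf), 0.7, tolerance = 1e-8)
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  ## one informative pattern repeated: AB vs CD split everywhere
  v <- matrix(rep(c(0, 0, 1, 1), 30), nrow = 4,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  v <- v + matrix(stats::rnorm(length(v), 0, 1e-6), nrow = 4)  # break ties
  b1 <- bootstrap_support(v, n_boot = 50, seed = 5)
  ## the A,B | C,D split is keyed by the side without the first tip
  expect_equal(unname(b1$support[["C|D"]]), 100)
  b2 <- bootstrap_support(v, n_boot = 50, seed = 5)
  expect_identical(b1$support, b2$support)
  expect_error(bootstrap_support(v, n_boot = 0), "n_boot")
})
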