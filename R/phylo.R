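#' Euclidean methylation divergence between two species vectors
#'
#' d(P,Q) = ((p1-q1)^2 + ... + (pn-qn)^2)^0.5 over the shared conserved-site
#' index.
#'
#' @param vec_p,vec_q equal-length numeric vectors without missing values.
#' @return the Euclidean distance.
#' @export
euclidean_distance <- function(vec_p, vec_q) {
  assert_that(length(vec_p) == length(vec_q),
              "vector length mismatch (%d vs %d)", length(vec_p), length(vec_q))
  assert_that(!anyNA(vec_p) && !anyNA(vec_q),
              "methylation vectors must not contain missing values")
  sqrt(sum((vec_p - vec_q)^2))
}

#' Per-species methylation level vectors over the conserved-site index
#'
#' For every quartet-map site and each subgenome copy (As, Ds), the pooled
#' (replicate-summed) methylation level of each species at its mapped
#' coordinate.  Diploid species contribute their single coordinate to both
#' copies; tetraploids contribute the As and Ds subgenome sites; the hybrid
#' contributes its A- and D-origin alleles.  Sites with a missing level in
#' any species are dropped (complete-case).
#'
#' @param panels named list of [methylome_panel()] objects.
#' @param site_map quartet site map.
#' @param coords named character vector: panel name -> "A", "D", "tet", "AD".
#' @param context restrict to one context (e.g. "CG"), or NULL for all.
#' @param min_coverage minimum pooled coverage per site (default 3).
#' @return numeric matrix, rows = species, columns = retained site copies.
#' @export
methylation_vectors <- function(panels, site_map, coords, context = "CG",
                                min_coverage = 3L) {
  ctx_sel <- context
  sm <- if (is.null(ctx_sel)) site_map else site_map[context == ctx_sel]
  mats <- lapply(names(panels), function(sp) {
    pooled <- panel_pooled_level(panels[[sp]], min_coverage)
    vals <- lapply(c("As", "Ds"), function(cp) {
      mc <- map_coords(sm, coords[[sp]], cp)
      idx <- pooled[mc, on = c("chrom", "pos", "strand"), which = TRUE]
      lv <- rep(NA_real_, nrow(mc))
      lv[!is.na(idx)] <- pooled$level[idx[!is.na(idx)]]
      lv
    })
    c(vals[[1]], vals[[2]])
  })
  mat <- do.call(rbind, mats)
  rownames(mat) <- names(panels)
  keep <- colSums(is.na(mat)) == 0
  mat[, keep, drop = FALSE]
}

#' Pairwise Euclidean distance matrix between species methylation vectors
#'
#' @param vectors numeric matrix (rows = species, >= 3) without missing
#'   values.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(vectors) {
  assert_that(nrow(vectors) >= 3,
              "need at least 3 species for a distance matrix (got %d)",
              nrow(vectors))
  dm <- as.matrix(stats::dist(vectors, method = "euclidean"))
  dimnames(dm) <- list(rownames(vectors), rownames(vectors))
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration.  On additive matrices the generating
#' topology and branch lengths are reconstructed exactly.  Equal Q-matrix
#' minima are broken deterministically by the lowest (row, column) index
#' pair.
#'
#' @param dm symmetric distance matrix with species dimnames.
#' @return an unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  assert_that(isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)),
              "distance matrix must be symmetric")
  n <- nrow(dm)
  assert_that(n >= 3, "neighbor joining needs >= 3 taxa")
  labels <- rownames(dm) %||% paste0("t", seq_len(n))
  sub <- labels  # newick fragment per active node
  d <- dm
  while (length(sub) > 3) {
    r <- length(sub)
    rs <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (i in seq_len(r - 1)) {
      for (j in seq.int(i + 1, r)) {
        q <- (r - 2) * d[i, j] - rs[i] - rs[j]
        if (q < best_q - 1e-12) {
          best_q <- q; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    newk <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], li, sub[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                   c(dk[keep], 0))
    sub <- c(sub[keep], newk)
    d <- d_new
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", sub[1], l1, sub[2], l2,
                 sub[3], l3)
  ape::read.tree(text = nwk)
}

## canonical bipartition keys of an unrooted tree: for each non-trivial
## split, the side not containing the alphabetically first tip, sorted and
## collapsed with "|"
tree_bipartitions <- function(tree) {
  ## radix sort: locale-independent canonical keys
  tips_all <- sort(tree$tip.label, method = "radix")
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) {
    p <- sort(labs[ix], method = "radix")
    if (length(p) < 2 || length(p) > length(tips_all) - 2) return(NA_character_)
    if (tips_all[1] %in% p) p <- sort(setdiff(tips_all, p), method = "radix")
    paste(p, collapse = "|")
  }, character(1))
  keys
}

#' Bootstrap support for the NJ methylation-divergence tree
#'
#' Resamples site columns with replacement, rebuilds the NJ tree for each
#' replicate, and reports for every internal bipartition of the full-data
#' tree the percentage of replicates containing it.
#'
#' @param vectors species x sites matrix ([methylation_vectors()]).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `tree` (the full-data NJ tree, bootstrap percentages in
#'   `node.label`) and `support` (named numeric vector keyed by bipartition).
#' @export
bootstrap_support <- function(vectors, n_boot = 1000L, seed = 1L) {
  assert_that(n_boot >= 1, "n_boot must be >= 1")
  assert_that(ncol(vectors) >= 1, "need at least one site column")
  full <- neighbor_joining(distance_matrix(vectors))
  keys <- tree_bipartitions(full)
  counts <- stats::setNames(rep(0, sum(!is.na(keys))), keys[!is.na(keys)])
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(vectors), replace = TRUE)
    bt <- neighbor_joining(distance_matrix(vectors[, cols, drop = FALSE]))
    bk <- tree_bipartitions(bt)
    hit <- names(counts)[names(counts) %in% bk]
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_boot
  node_label <- rep("", tree_n_internal(full))
  for (i in seq_along(keys)) {
    node_label[i] <- if (is.na(keys[i])) "" else
      sprintf("%g", support[[keys[i]]])
  }
  full$node.label <- node_label
  list(tree = full, support = support)
}

tree_n_internal <- function(tree) tree$Nnode
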