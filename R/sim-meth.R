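#' Evolve two-state methylation along a species tree
#'
#' Each site is methylated or unmethylated; along a branch of length b an
#' unmethylated site gains methylation with probability 1 - exp(-gain * b)
#' and a methylated site loses it with probability 1 - exp(-loss * b), with
#' context-specific gain/loss rates.
#'
#' @param tree an [ape::phylo] object or newick string; tip labels name the
#'   species.
#' @param base_states logical vector of root states.
#' @param contexts character vector (CG/CHG/CHH) parallel to `base_states`.
#' @param rates named list per context with elements `gain` and `loss`.
#' @param seed optional RNG seed.
#' @return named list of tip-state logical vectors.
#' @export
evolve_methylation <- function(tree, base_states, contexts, rates, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  assert_that(!is.null(tree$edge.length) && all(tree$edge.length >= 0),
              "branch lengths must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "cladewise")
  states_at <- vector("list", max(tree$edge))
  states_at[[n_tip + 1L]] <- base_states
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    states_at[[child]] <- evolve_branch(states_at[[parent]], contexts, rates,
                                        tree$edge.length[k])
  }
  stats::setNames(states_at[seq_len(n_tip)], tree$tip.label)
}

## flip states along one branch
evolve_branch <- function(states, contexts, rates, b) {
  assert_that(b >= 0, "branch lengths must be non-negative")
  if (b == 0) return(states)
  out <- states
  for (ctx in unique(contexts)) {
    idx <- which(contexts == ctx)
    r <- rates[[ctx]]
    p_gain <- 1 - exp(-r[["gain"]] * b)
    p_loss <- 1 - exp(-r[["loss"]] * b)
    u <- stats::runif(length(idx))
    flip <- ifelse(states[idx], u < p_loss, u < p_gain)
    out[idx] <- xor(states[idx], flip)
  }
  out
}

#' Evolve the full species panel of methylation states with spiked features
#'
#' Produces per-species methylation states and true per-site probabilities
#' for the whole panel: the diploids drift from a shared root, the F1
#' hybrid carries both (unchanged) parental allele states with its CHH
#' probabilities reduced by the configured factor, and the tetraploid
#' subgenomes start from the extant diploid states, share a polyploid stem
#' branch, and then radiate along the configured species tree.  Ground
#' truth features are spiked at known windows/genes: hybrid-induced CG DMRs
#' propagated to each wild tetraploid with the maintenance probability
#' (domesticated forms inherit their wild progenitor's flag), cDMR/hDMC
#' windows inside ortholog gene bodies, wild-vs-cultivated epiallele DMRs
#' (shared and species-private), methylation-shifted genes in wGh, and
#' gene-loss pairs with elevated diploid non-CG gene-body methylation.
#'
#' @param genomes a [simulate_genomes()] object.
#' @param seed RNG seed.
#' @param spike logical; disable all feature spiking with `FALSE`.
#' @return list (class `polymeth_sim_meth`) with `states`, `prob` (per
#'   species; tetraploids ordered As sites then Ds sites, matching the
#'   tetraploid site table), `spikes` (ground-truth tables) and `windows`
#'   (the spike-eligible window table).
#' @export
simulate_methylomes <- function(genomes, seed = genomes$cfg$seed + 1L,
                                spike = TRUE) {
  cfg <- genomes$cfg
  set.seed(seed)
  sA <- genomes$sites_A; sD <- genomes$sites_D
  tm <- genomes$truth_map

  ## ---- shared root states ---------------------------------------------
  u_A <- stats::runif(nrow(sA))
  u_D <- stats::runif(nrow(sD))
  u_shared <- stats::runif(nrow(tm))
  u_A[tm$idx_A] <- u_shared
  u_D[tm$idx_D] <- u_shared
  root_A <- u_A < root_prob_of(sA, cfg)
  root_D <- u_D < root_prob_of(sD, cfg)

  ## ---- diploid drift ---------------------------------------------------
  state_A <- evolve_branch(root_A, sA$context, cfg$rates, cfg$diploid_branch)
  state_D <- evolve_branch(root_D, sD$context, cfg$rates, cfg$diploid_branch)

  ## ---- spike selection -------------------------------------------------
  spikes <- list()
  if (spike) {
    sel <- select_spike_targets(genomes, cfg)
    spikes <- sel$spikes
    ## stage 1: diploid-level forcing (before hybrid/tetraploid stages)
    st <- apply_pre_spikes(state_A, state_D, sA, sD, tm, sel, cfg)
    state_A <- st$state_A; state_D <- st$state_D
  }

  ## ---- hybrid: union of current parental alleles -----------------------
  hybrid <- list(A = state_A, D = state_D)

  ## ---- tetraploid radiation -------------------------------------------
  crown_As <- evolve_branch(state_A, sA$context, cfg$rates, cfg$tet_stem)
  crown_Ds <- evolve_branch(state_D, sD$context, cfg$rates, cfg$tet_stem)
  tips_As <- evolve_methylation(cfg$tet_tree, crown_As, sA$context, cfg$rates)
  tips_Ds <- evolve_methylation(cfg$tet_tree, crown_Ds, sD$context, cfg$rates)
  tets <- stats::setNames(lapply(SIM_TETRAPLOIDS, function(sp) {
    list(As = tips_As[[sp]], Ds = tips_Ds[[sp]])
  }), SIM_TETRAPLOIDS)

  ## ---- stage 2: post-drift forcing ------------------------------------
  if (spike) {
    ps <- apply_post_spikes(tets, hybrid, tm, spikes, cfg,
                            genomes$sites_A$gene_id)
    tets <- ps$tets; hybrid <- ps$hybrid; spikes <- ps$spikes
  }

  ## ---- probabilities ---------------------------------------------------
  lv <- function(states, contexts) {
    ifelse(states, cfg$level_methylated[contexts], cfg$level_unmethylated[contexts])
  }
  prob <- list(
    A = lv(state_A, sA$context),
    D = lv(state_D, sD$context),
    A2D5 = {
      p <- c(lv(hybrid$A, sA$context), lv(hybrid$D, sD$context))
      ctx <- c(sA$context, sD$context)
      p[ctx == "CHH"] <- p[ctx == "CHH"] * cfg$chh_reduction
      p
    })
  for (sp in SIM_TETRAPLOIDS) {
    prob[[sp]] <- c(lv(tets[[sp]]$As, sA$context), lv(tets[[sp]]$Ds, sD$context))
  }
  structure(list(states = list(A = state_A, D = state_D, hybrid = hybrid,
                               tets = tets),
                 prob = prob, spikes = spikes,
                 seed = seed),
            class = "polymeth_sim_meth")
}

## probability that each site starts methylated at the root, by class
root_prob_of <- function(sites, cfg) {
  out <- numeric(nrow(sites))
  for (ctx in VALID_CONTEXTS) {
    idx <- sites$context == ctx
    out[idx] <- cfg$root_prob[[ctx]][sites$class[idx]]
  }
  out
}

## choose disjoint spike windows and genes
select_spike_targets <- function(genomes, cfg) {
  tm <- genomes$truth_map
  cg <- tm[context == "CG"]
  cg[, win := window_of(chrom_As, pos_As, 100L)]
  wins <- cg[, .(n_sites = .N, gene_id = {
    gid <- genomes$sites_A$gene_id[idx_A]
    gid <- gid[!is.na(gid)]
    if (length(gid)) gid[1] else NA_character_
  }), by = win]
  elig <- wins[n_sites >= cfg$spike_min_sites]
  genes <- genomes$gene_meta$gene_id
  need_genes <- cfg$n_hdmc + cfg$n_cdmr + cfg$n_hyper_genes +
    cfg$n_hypo_genes + cfg$n_lost_pairs
  assert_that(length(genes) >= need_genes,
              "config error: %d ortholog genes available but %d needed for spiked features",
              length(genes), need_genes)
  gene_wins_all <- elig[!is.na(gene_id)][order(gene_id, -n_sites)][
    !duplicated(gene_id)]
  gene_pool <- sample(intersect(genes, gene_wins_all$gene_id))
  assert_that(length(gene_pool) >= need_genes,
              "config error: %d genes with eligible spike windows but %d needed",
              length(gene_pool), need_genes)
  take_genes <- function(n) {
    out <- gene_pool[seq_len(n)]
    gene_pool <<- gene_pool[-seq_len(n)]
    out
  }
  ## one eligible body window per gene (largest CG count)
  gene_wins <- gene_wins_all
  pick_gene_windows <- function(ids) {
    w <- gene_wins[gene_id %in% ids]
    w$win
  }
  hdmc_genes <- take_genes(cfg$n_hdmc)
  cdmr_genes <- take_genes(cfg$n_cdmr)
  hyper_genes <- take_genes(cfg$n_hyper_genes)
  hypo_genes <- take_genes(cfg$n_hypo_genes)
  lost_genes <- take_genes(cfg$n_lost_pairs)
  hdmc_wins <- pick_gene_windows(hdmc_genes)
  cdmr_wins <- pick_gene_windows(cdmr_genes)
  used <- c(hdmc_wins, cdmr_wins)
  free <- setdiff(elig[is.na(gene_id), win], used)
  need_free <- cfg$n_hybrid_dmrs + cfg$n_epi_shared + 2L * cfg$n_epi_private
  assert_that(length(free) >= need_free,
              "config error: %d intergenic spike windows available but %d needed",
              length(free), need_free)
  free <- sample(free)
  take_wins <- function(n) {
    out <- free[seq_len(n)]
    free <<- free[-seq_len(n)]
    out
  }
  hyb_wins <- take_wins(cfg$n_hybrid_dmrs)
  epi_shared <- take_wins(cfg$n_epi_shared)
  epi_gh <- take_wins(cfg$n_epi_private)
  epi_gb <- take_wins(cfg$n_epi_private)
  alt_dir <- function(n) rep(c("hyper", "hypo"), length.out = n)
  spikes <- list(
    hybrid_dmrs = data.table::data.table(
      win_id = hyb_wins, context = "CG", direction = alt_dir(length(hyb_wins))),
    cdmr_hdmc = data.table::rbindlist(list(
      data.table::data.table(win_id = gene_wins[gene_id %in% hdmc_genes, win],
                             gene_id = gene_wins[gene_id %in% hdmc_genes, gene_id],
                             class = "hDMC"),
      data.table::data.table(win_id = gene_wins[gene_id %in% cdmr_genes, win],
                             gene_id = gene_wins[gene_id %in% cdmr_genes, gene_id],
                             class = "cDMR"))),
    epialleles = data.table::rbindlist(list(
      data.table::data.table(win_id = epi_shared, scope = "shared",
                             direction = alt_dir(length(epi_shared))),
      data.table::data.table(win_id = epi_gh, scope = "Gh",
                             direction = alt_dir(length(epi_gh))),
      data.table::data.table(win_id = epi_gb, scope = "Gb",
                             direction = alt_dir(length(epi_gb))))),
    shifted_genes = data.table::data.table(
      gene_id = c(hyper_genes, hypo_genes),
      direction = c(rep("hyper", length(hyper_genes)),
                    rep("hypo", length(hypo_genes)))),
    lost_pairs = data.table::data.table(
      pair_id = lost_genes,
      gene_a = lost_genes, gene_d = lost_genes,
      lost = rep(c("A", "D"), length.out = length(lost_genes)))
  )
  ## direction of the diploid difference for cDMR/hDMC windows
  spikes$cdmr_hdmc[, direction := rep(c("A_high", "D_high"),
                                      length.out = .N)]
  list(spikes = spikes, win_sites = cg)
}

## diploid-level (pre-hybrid) state forcing
apply_pre_spikes <- function(state_A, state_D, sA, sD, tm, sel, cfg) {
  cg <- sel$win_sites
  spikes <- sel$spikes
  win_idx <- function(wins) cg[win %in% wins, .(idx_A, idx_D, win)]
  ## cDMR/hDMC: plant the diploid A-vs-D difference
  for (dirn in c("A_high", "D_high")) {
    wi <- win_idx(spikes$cdmr_hdmc[direction == dirn, win_id])
    if (dirn == "A_high") {
      state_A[wi$idx_A] <- TRUE; state_D[wi$idx_D] <- FALSE
    } else {
      state_A[wi$idx_A] <- FALSE; state_D[wi$idx_D] <- TRUE
    }
  }
  ## hybrid DMR windows: fix the parental baseline opposite to the planned
  ## hybrid state (hyper DMR: parent unmethylated)
  for (dirn in c("hyper", "hypo")) {
    wi <- win_idx(spikes$hybrid_dmrs[direction == dirn, win_id])
    state_A[wi$idx_A] <- (dirn == "hypo")
    state_D[wi$idx_D] <- (dirn == "hypo")
  }
  ## epiallele windows: wild baseline opposite the cultivated state
  for (dirn in c("hyper", "hypo")) {
    wi <- win_idx(spikes$epialleles[direction == dirn, win_id])
    state_A[wi$idx_A] <- (dirn == "hypo")
    state_D[wi$idx_D] <- (dirn == "hypo")
  }
  ## shifted genes: diploid body CG baseline opposite the tetraploid state
  gene_body_idx <- function(ids, sites) {
    which(!is.na(sites$gene_id) & sites$gene_id %in% ids &
            sites$context == "CG")
  }
  hyper_ids <- spikes$shifted_genes[direction == "hyper", gene_id]
  hypo_ids <- spikes$shifted_genes[direction == "hypo", gene_id]
  state_A[gene_body_idx(hyper_ids, sA)] <- FALSE
  state_A[gene_body_idx(hypo_ids, sA)] <- TRUE
  ## lost pairs: elevated non-CG body methylation on the lost copy's diploid
  noncg_body_idx <- function(ids, sites) {
    which(!is.na(sites$gene_id) & sites$gene_id %in% ids &
            sites$context %in% c("CHG", "CHH"))
  }
  lost_a <- spikes$lost_pairs[lost == "A", gene_a]
  lost_d <- spikes$lost_pairs[lost == "D", gene_d]
  ia <- noncg_body_idx(lost_a, sA)
  id_ <- noncg_body_idx(lost_d, sD)
  state_A[ia] <- stats::runif(length(ia)) < 0.8
  state_D[id_] <- stats::runif(length(id_)) < 0.8
  list(state_A = state_A, state_D = state_D)
}

## post-drift forcing on hybrid and tetraploid states.  gene_of_idx_a maps
## rows of the A site table to their gene id (NA outside gene bodies).
apply_post_spikes <- function(tets, hybrid, tm, spikes, cfg, gene_of_idx_a) {
  cg <- data.table::copy(tm[context == "CG"])
  cg[, win := window_of(chrom_As, pos_As, 100L)]
  cg[, gene := gene_of_idx_a[idx_A]]
  win_idx <- function(wins) cg[win %in% wins, .(idx_A, idx_D, win)]

  ## hybrid DMRs: force the hybrid A-allele state, then propagate to each
  ## wild tetraploid with the maintenance probability (cultivated forms
  ## inherit the wild progenitor's flag)
  hyb <- spikes$hybrid_dmrs
  for (w in seq_len(nrow(hyb))) {
    wi <- win_idx(hyb$win_id[w])
    target <- hyb$direction[w] == "hyper"
    hybrid$A[wi$idx_A] <- target
  }
  maint <- matrix(stats::runif(nrow(hyb) * length(SIM_WILD_TETRAPLOIDS)) <
                    cfg$maintenance_prob,
                  nrow = nrow(hyb), ncol = length(SIM_WILD_TETRAPLOIDS),
                  dimnames = list(NULL, SIM_WILD_TETRAPLOIDS))
  flags <- cbind(maint, cGh = maint[, "wGh"], cGb = maint[, "wGb"])
  colnames(flags) <- c(SIM_WILD_TETRAPLOIDS, "cGh", "cGb")
  for (w in seq_len(nrow(hyb))) {
    wi <- win_idx(hyb$win_id[w])
    target <- hyb$direction[w] == "hyper"
    for (sp in colnames(flags)) {
      if (flags[w, sp]) tets[[sp]]$As[wi$idx_A] <- target
    }
  }
  spikes$hybrid_dmrs <- cbind(hyb, data.table::as.data.table(flags))

  ## cDMR / hDMC: force the subgenome pattern in every tetraploid
  ch <- spikes$cdmr_hdmc
  for (w in seq_len(nrow(ch))) {
    wi <- win_idx(ch$win_id[w])
    a_high <- ch$direction[w] == "A_high"
    as_state <- if (ch$class[w] == "cDMR") a_high else !a_high
    ds_state <- !as_state
    for (sp in SIM_TETRAPLOIDS) {
      tets[[sp]]$As[wi$idx_A] <- as_state
      tets[[sp]]$Ds[wi$idx_D] <- ds_state
    }
  }

  ## epialleles: force cultivated-vs-wild difference on the As subgenome
  epi <- spikes$epialleles
  for (w in seq_len(nrow(epi))) {
    wi <- win_idx(epi$win_id[w])
    cult <- epi$direction[w] == "hyper"
    scope <- epi$scope[w]
    if (scope %in% c("shared", "Gh")) {
      tets$cGh$As[wi$idx_A] <- cult
      tets$wGh$As[wi$idx_A] <- !cult
    }
    if (scope %in% c("shared", "Gb")) {
      tets$cGb$As[wi$idx_A] <- cult
      tets$wGb$As[wi$idx_A] <- !cult
    }
  }

  ## methylation-shifted genes in wGh (As subgenome gene bodies)
  sg <- spikes$shifted_genes
  for (dirn in c("hyper", "hypo")) {
    ids <- sg[direction == dirn, gene_id]
    idx <- which(!is.na(cg$gene) & cg$gene %in% ids)
    tets$wGh$As[cg$idx_A[idx]] <- (dirn == "hyper")
  }
  list(tets = tets, hybrid = hybrid, spikes = spikes)
}
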