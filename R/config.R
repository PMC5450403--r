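#' Analysis configuration with the standard default thresholds
#'
#' Collects every tunable cut-off used by the pipeline in one list.
#' Defaults: DmCs require an
#' absolute methylation-level change of at least 0.5 at ANOVA P < 0.01; DMRs
#' use 100-bp windows (>= 4 CG/CHG or >= 16 CHH cytosines covered by >= 3
#' reads), ANOVA P < 0.05 and level cut-offs 0.5 (CG, CHG) / 0.2 (CHH);
#' hybrid-DMR maintenance thresholds are 0.4 (CG, CHG) / 0.1 (CHH);
#' homoeologous cDMR/hDMC and methylation-shifted gene calls use |delta| >
#' 0.6 in CG; gene-body binomial classification uses P < 0.05, with genes
#' requiring > 40% of body cytosines covered by >= 3 reads; alignment blocks
#' are kept at first-pass score > 500, final score > 2000 and length >= 2 kb.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `polymeth_config`.
#' @examples
#' cfg <- pipeline_config(dmr_alpha = 0.01)
#' cfg$dmc_delta
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_coverage          = 3L,
    dmc_delta             = 0.5,
    dmc_p                 = 0.01,
    dmr_window            = 100L,
    dmr_step              = 100L,   # non-overlapping tiles by default
    dmr_alpha             = 0.05,
    dmr_delta_cg_chg      = 0.5,
    dmr_delta_chh         = 0.2,
    dmr_min_sites_cg_chg  = 4L,
    dmr_min_sites_chh     = 16L,
    conservation_delta    = c(CG = 0.4, CHG = 0.4, CHH = 0.1),
    min_score_first       = 500,
    min_score_final       = 2000,
    min_region_len        = 2000L,
    g_confirm_min_reads   = 3L,
    homoeolog_delta       = 0.6,
    shifted_gene_delta    = 0.6,
    body_binom_p          = 0.05,
    ortholog_coverage_frac = 0.4,
    nonconversion_rate    = 0.005,
    site_call             = "binomial",  # or "level:0.5"
    deg_fold_change       = 2,
    deg_alpha             = 0.01,
    bias_log2_shift       = 1,
    bias_alpha            = 0.05,
    expr_pseudocount      = 0.1,
    promoter_len          = 2000L,
    window_site_mean      = FALSE,  # pooled-read window mean by default
    merge_symmetric_cg    = FALSE,
    bootstrap_n           = 1000L,
    seed                  = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  assert_that(length(unknown) == 0,
              "unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = c("polymeth_config", "list"))
}

validate_config <- function(cfg) {
  assert_that(cfg$min_coverage >= 1, "min_coverage must be >= 1")
  assert_that(cfg$dmc_delta >= 0 && cfg$dmc_delta <= 1, "dmc_delta must be in [0,1]")
  assert_that(cfg$dmc_p > 0 && cfg$dmc_p <= 1, "dmc_p must be in (0,1]")
  assert_that(cfg$dmr_window >= 1, "dmr_window must be >= 1")
  assert_that(all(cfg$conservation_delta >= 0 & cfg$conservation_delta <= 1),
              "conservation_delta values must be in [0,1]")
  assert_that(cfg$nonconversion_rate >= 0 && cfg$nonconversion_rate < 1,
              "nonconversion_rate must be in [0,1)")
  invisible(cfg)
}

#' Read or write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a `polymeth_config` list (for writing).
#' @return `read_config()` returns a `polymeth_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$conservation_delta)) {
    raw$conservation_delta <- unlist(raw$conservation_delta)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
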