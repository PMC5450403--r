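---
title: "Comparative methylome analysis of polyploid species panels with polymeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative methylome analysis of polyploid species panels with polymeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymeth)
```

## The scientific setting

polymeth analyses whole-genome bisulfite methylomes across a panel that
recapitulates allopolyploid crop evolution: two diploid progenitors (an
A-genome and a D-genome species), their interspecific F1 hybrid, five wild
allotetraploid species carrying both subgenomes (As and Ds), and two
independently domesticated forms. The questions the package addresses are
those of comparative polyploid epigenomics:

* How fast does DNA methylation diverge relative to nucleotide substitution,
  and does genome-wide methylation divergence recapitulate the species
  phylogeny?
* Are methylation changes induced by interspecific hybridization maintained
  through millions of years of allopolyploid evolution?
* How do homoeologous (As vs Ds) methylation differences relate to the
  ancestral diploid (A vs D) differences, and do reversals (hDMCs) bias
  homoeolog expression?
* Which methylation differences between wild and cultivated accessions are
  shared across independently domesticated species — candidate epialleles
  selected during domestication?

Every analysis runs on *conserved cytosines*: positions that are cytosines
of identical sequence context in all compared genomes, extracted from
pairwise alignment blocks, so that C/T nucleotide variation between species
cannot masquerade as methylation change.

## Data model and statistics

**Site levels.** Bisulfite read counts per cytosine give the methylation
level C/(C+T). Sites need at least 3 reads in every biological replicate;
the panel design assumes two replicates per species, which is also the
replication the ANOVA-based tests expect.

**DmCs.** A differentially methylated cytosine between two species requires
an absolute difference in species mean levels of at least 0.5 and one-way
ANOVA p < 0.01 across the four replicate levels (df 1, 2). With two
replicates per group the ANOVA has little power against small shifts, which
is precisely why the paired |delta| >= 0.5 filter carries most of the
specificity. Degenerate inputs follow the limits of the F statistic: zero
within-group variance with unequal means gives p = 0; four equal values
give p = 1. No multiple-testing correction is applied: the thresholds are
raw-p cut-offs by design, and the delta filter dominates the false-positive
behaviour (the null-calibration benchmark quantifies this).

**DMRs.** Fixed 100-bp windows ("sliding" implemented as non-overlapping
consecutive tiles; the step is configurable but tiling avoids
double-counting windows as separate regions). A window is eligible when it
contains at least 4 CG or CHG cytosines, or 16 CHH cytosines, each covered
by >= 3 reads in every replicate. The replicate window level is the
pooled-read (coverage-weighted) mean sum(C)/sum(C+T) — more stable at low
coverage than the mean of site levels, which remains available via
`site_mean = TRUE`. A DMR requires ANOVA p < 0.05 on the four replicate
window levels plus an absolute group-mean difference of 0.5 (CG, CHG) or
0.2 (CHH). Adjacent significant windows are not merged; each window is one
record, so counts are window counts.

**Hybrid DMR maintenance.** Hybrid-vs-parent DMRs are called per subgenome:
the hybrid's A-origin alleles are compared against the A parent at mapped
coordinates and likewise for D (the "mid-parent" is the corresponding
parent at each locus). A hybrid DMR counts as conserved in a tetraploid
when the tetraploid-minus-parent window delta has the same sign and
absolute value >= 0.4 (CG, CHG) or 0.1 (CHH). Fractions conserved in at
least one and in all wild tetraploids are reported with an upper-tail
hypergeometric enrichment p against the background rate of such same-sign
changes among all eligible windows.

**Methylation phylogeny.** Per species, conserved-site levels form a vector
P = (p1...pn); pairwise Euclidean distances build the distance matrix and a
neighbor-joining tree with site-resampling bootstrap. The NJ implementation
is the standard Saitou–Nei agglomeration with a deterministic lowest-index
tie-break; on additive matrices it reconstructs the generating topology and
branch lengths exactly (verified against full topology enumeration for
small n, and against an independent reference implementation). Each
tetraploid contributes both subgenome levels at every conserved site —
the site index runs over (site, subgenome copy) pairs, with diploids
contributing their single coordinate to both copies — so species are tips
and subgenomes are vector coordinates. Sites missing a level in any
species are dropped (complete-case), matching the "conserved in all
species" construction. CG and non-CG trees are built separately.

**Gene-body methylation.** Individual sites are called methylated by a
one-sided binomial test against the bisulfite non-conversion rate (default
0.005), the standard single-methylome convention, with a plain level
threshold available via `method = "level:0.5"`. Genes are then classified by a binomial test of
their m methylated body cytosines out of n callable ones against the
genome-wide methylated fraction for that context: CG body-methylated when
P_CG < 0.05, CG body-unmethylated when P_CG > 0.95, excluded when
P_CHG < 0.05 or P_CHH < 0.05 (removing non-CG-methylated genes) or when
fewer than 40% of body cytosines are callable. The epimutation-rate proxy
for an ortholog pair is the number of DmCGs in the body divided by the
total CG count, compared against Ks.

**Ks.** Nei–Gojobori (1986) codon-pathway counting with Jukes–Cantor
correction, Ks = -3/4 ln(1 - 4/3 ps). NG86 is the simplest standard
estimator and therefore the default; externally computed Ks values can be
supplied instead. Conventions: changes creating stop codons count as
nonsynonymous in the site census; pathways through stop codons are excluded
from the average (if every pathway is blocked, all are used with stop steps
counted nonsynonymous). Saturated divergence (ps >= 3/4) returns NA.

**Homoeolog classes.** Windows with |mCG_A - mCG_D| > 0.6 in the diploids
are classified by the tetraploid subgenomes: cDMR when mCG_As - mCG_Ds has
the same sign and magnitude > 0.6, hDMC when the sign is reversed at the
same magnitude, otherwise neither. Expression bias of a homoeolog pair is a
shift of the As/Ds ratio away from the diploid A/D ratio: |log2 ratio
shift| > 1 together with ANOVA p < 0.05 on the per-replicate log ratios —
a package decision mirroring the DEG rule (>2-fold change and ANOVA
p < 0.01 on two replicates); a Fisher-style count test would be a
reasonable alternative. Ratios are pseudocounted with 0.1
RPKM.

**Epialleles.** The two domestication comparisons (cultivated vs wild in
each species) are intersected by window identity on the shared reference;
shared same-direction DMRs overlapping a gene body or its 2-kb promoter
yield candidates. Window-identity intersection is the strictest reading of
"shared"; promoter inclusion defaults to on because regulatory epialleles
commonly act through promoter methylation, and both choices are flags.

## The synthetic methylome simulator

`simulate_panel()` generates the full study design with complete ground
truth, so every stage has recovery benchmarks. What it emulates:

* **Genomes.** Alternating conserved tracts (>= 2 kb, identical between A
  and D, copied into the As/Ds subgenomes of the tetraploid reference) and
  diverged tracts. Alignment-block files encode the planted homology
  exactly, plus decoy blocks (short-but-strong, long-but-weak) that the
  score/uniqueness/length filter must reject. One ortholog gene per
  conserved tract; TE annotations placed per genome with a higher genic TE
  fraction in D than in A.
* **Methylation.** A two-state (methylated/unmethylated) per-site process
  with context-specific gain/loss rates; partial levels arise only from the
  cell-mixture ceiling (0.90/0.80/0.45 for CG/CHG/CHH) and read sampling.
  This is the simplest process consistent with the bimodal CG levels the
  gene-body binomial classifier assumes. Diploids drift from a shared root
  (branch length 3 each); the tetraploid subgenomes start from the extant
  diploid states, share a polyploid stem (0.5), and radiate along the
  nested species tree with the (Gh,Gt) and (Gb,Gd) sister pairs and
  domesticated forms nested inside their wild lineages. The F1 hybrid
  carries both parental allele states unchanged, with CHH probabilities
  multiplied by 0.8 — hybrid CHH reduction is modelled as directional
  only, so the magnitude is a configurable placeholder.
* **Ground truth spikes.** Hybrid-induced CG DMRs propagated to each wild
  tetraploid independently with maintenance probability 0.8 (domesticated
  forms inherit their progenitor's state); cDMR/hDMC windows planted inside
  ortholog gene bodies; wild-vs-cultivated epiallele DMRs split into shared
  and species-private sets (defaults 30/170, i.e. ~15% of domestication
  DMRs shared between the two species); methylation-shifted genes; gene-loss
  pairs with elevated diploid non-CG body methylation on the lost copy.
* **Reads.** Coverage ~ Poisson(20) per site and replicate; methylated
  reads ~ Binomial(coverage, p(1-err)+(1-p)err) with err = 0.005;
  complementary-strand guanine confirmation as an independent Poisson draw.
* **Expression.** log2 expression = baseline - 0.5 x (body CG level - 0.2)
  plus lognormal replicate noise; hDMC genes receive a planted homoeolog
  bias (probability 0.85, log2 shift 3, direction following the methylation
  reversal), other spiked genes at the 0.05 background rate.

What the simulator does **not** emulate — hence what green benchmarks do
not show about real data: sequencing and mapping biases, partially
methylated domains and intermediate cell-mixture levels, non-independent
sites (RdDM spreading), indel-containing alignments, genuinely unknown
progenitors, and expression variation beyond lognormal noise. Recovery
rates on simulated panels are upper bounds for real-data performance.

## Problem sizes and numerical choices

The default panel is 2 chromosomes x 700 kb with every cytosine tracked
(~475k stranded cytosines per diploid genome, ~40k conserved CG sites),
sized so that the default spiked-feature counts (200 hybrid DMRs, 200
cDMRs, 50 hDMCs, 30+340 epiallele windows, 70 shifted genes, 40 lost
pairs) each have a dedicated ortholog gene or intergenic window. The
benchmark suites use smaller purpose-built configurations: oracle and
null-calibration checks run on flat 10k-site two-species panels; the
phylogeny benchmark uses 2 x 150 kb panels with 6000 subsampled CG site
columns and 200 bootstrap replicates over 20 seeded replicates; the
maintenance benchmark turns tetraploid drift off so the closed forms
0.8^5 and 1 - 0.2^5 apply exactly. The full pipeline on the default panel
completes in a few minutes on one CPU.

Numerical conventions: all internal coordinates are 0-based half-open with
conversion only at the I/O boundary (CX reports 1-based, BED 0-based, GFF3
1-based); symmetric CG sites are kept as separate stranded records (strand merging
is a flag, off by default); NJ ties break on the lowest index pair; overlap ties between
equal-score alignment blocks break on (chromosome, start); the exact
Wilcoxon signed-rank null is built by dynamic programming over doubled
midranks for up to 25 informative pairs, so ties still get exact p-values;
hypergeometric tails are computed in log space. Every randomized procedure
takes an explicit seed, and `run_full_pipeline()` derives per-stage child
seeds from one master seed so stages can be re-run independently yet
reproducibly — two runs with the same seed produce byte-identical reports.

## A short tour

```{r tour, eval = FALSE}
library(polymeth)

## simulate a small panel and run the whole workflow
cfg <- sim_config(n_chromosomes = 1L, chrom_length = 150000L,
                  n_hybrid_dmrs = 10L, n_cdmr = 8L, n_hdmc = 6L,
                  n_epi_shared = 4L, n_epi_private = 6L,
                  n_hyper_genes = 4L, n_hypo_genes = 2L, n_lost_pairs = 6L)
report <- run_full_pipeline(cfg, pipeline_config(), seed = 7,
                            out_dir = "run1", bootstrap_n = 100L)
report$recovery

## or drive the stages yourself
sim <- simulate_panel(cfg, seed = 7)
dmcs <- call_dmcs(sim$panels$A, sim$panels$D,
                  site_map = sim$truth$site_map,
                  coords_a = "A", coords_b = "D")
hom <- classify_cdmr_hdmc(sim$panels$A, sim$panels$D, sim$panels$wGh,
                          sim$truth$site_map)
table(hom$class)
```

## Known limitations

* The statistical operations assume exactly two biological replicates per
  species (the panel design); `one_way_anova()` itself is general, but the
  vectorised site/window paths are 2+2 only.
* DMR windows are fixed tiles; a true sliding step or adjacent-window
  merging would change counts and is deliberately not the default.
* The simulator's two-state methylation model cannot produce intermediate
  stable levels, so classifier performance on partially methylated genes is
  untested.
* Ks estimation assumes a gap-free codon alignment; alignment itself is out
  of scope.
* The conserved-region step models the alignment *filtering* contract
  (score > 500 first pass, 1-to-1 uniqueness, score > 2000, >= 2 kb);
  running a genome aligner is out of scope, and real alignment blocks must
  be provided in the MAF-like format described in `read_alignment_blocks()`.
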