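---
title: "Methods: quantifying an augmented wild-type signature across omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying an augmented wild-type signature across omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

A catalytically dead kinase mutant can still drive a phenotype if the
mutation traps the protein in an effector-competent conformation. The
analyses in this package target exactly that situation for PKC&alpha;
D463H: a kinase-dead substitution whose cellular output looks like an
*amplified* copy of the wild-type (WT) program rather than a loss or a
novel program, while a second substitution at the same residue (D463N)
behaves as a plain loss of function. Three independent data layers carry
the evidence:

1. **Transcriptome.** Bulk RNA-seq of parental cells and cells expressing
   WT, D463H ("DH") or D463N ("DN") protein. The claim has two measurable
   parts: genes perturbed by DH move in the *same direction* as under WT
   (direction concordance), and they move roughly *twice as far* on the
   log2 scale (amplitude ratio near 2).
2. **Interactome.** AP-MS pull-downs of the three tagged constructs plus
   empty-vector controls, quantified label-free. The DH-specific gain
   shows up as binders recovered exclusively with DH, and binders enriched
   with DH over WT beyond a log2 fold-change threshold.
3. **Predicted structure ensembles.** Confidence output (PAE matrices,
   pTM) of a structure-prediction ensemble per construct. An autoinhibited
   ("PS-in") conformer has a confidently placed pseudosubstrate against
   the kinase domain; an open ("PS-out") conformer instead has the C2
   domain confidently packed there. Class fractions per construct
   summarize the predicted conformational landscape.

The deposited datasets of the original study are not shipped; every stage
instead runs against a synthetic generator with known ground truth, so
each claim is tested by parameter recovery.

## Differential expression engine

The engine is a compact negative-binomial Wald pipeline:

* **Normalization** by median-of-ratios: per sample, the median over
  always-expressed genes of the count to per-gene geometric mean ratio,
  rescaled to geometric mean 1. This anchors fold changes on the unchanged
  majority of genes; simulations in the tests keep most genes null (or
  symmetric in effect sign) for the same reason any real design should.
* **Dispersions**: a per-gene method-of-moments estimate
  `max(0, (s2 - m)/m2)` on normalized counts pooled across condition
  groups by degrees of freedom, a robust `a0 + a1/mu` mean trend
  (`MASS::rlm`), and a final value shrinking the raw estimate halfway to
  the trend on the log scale. Genes whose raw estimate truncates at zero
  carry no usable excess-variance information at n = 2 or 3; they take the
  trend value outright. Shrinking them toward the `1e-8` floor instead
  would treat them as near-Poisson and demonstrably inflates type-I error.
* **Per-gene GLM**: log-link NB regression (`~ condition` or
  `~ condition + batch`) at fixed dispersion, fitted by IRLS (at most 50
  iterations, coefficient tolerance `1e-8`, linearly aliased batch columns
  dropped, non-converged genes reported as `NA`). Log size factors enter
  as offsets.
* **Inference**: Wald statistic `log2fc / se`. The reference is a
  moderated t with `d / (1 - w)^2` degrees of freedom, where `d` is the
  pooled within-condition df behind the dispersion model and `w = 0.5`
  the shrinkage weight: averaging log dispersions halves the sd of the
  log-dispersion error, so the effective df quadruple. With a plain
  standard-normal reference the pure-null false-positive rate at
  `p < 0.05` measured ~0.07 at the test's simulation scale; with the
  moderated t it sits at ~0.05-0.06, inside the 0.035-0.065 band the test
  suite enforces. Benjamini-Hochberg adjustment excludes `NA` genes.

Deliberate simplifications, documented rather than hidden: no independent
filtering, no outlier (Cook's) handling, no posterior LFC shrinkage - the
concordance and amplitude statistics are defined on raw maximum-likelihood
LFCs, and shrunk LFCs would bias the amplitude ratio toward 1. Batch is a
model covariate for inference; expression matrices for PCA/heatmaps are
batch-corrected separately (`limma::removeBatchEffect` behind
`remove_batch_effect()`), never fed back into testing.

## Pattern clustering and the two headline statistics

Each gene lands in one of 8 patterns according to which of the three
contrasts against parental are significant at `padj < alpha` (default
0.05, the conventional threshold for this tool family). Over a chosen
cluster (the D463H-only cluster is the interesting one):

* `frac_same_direction`: fraction of genes with `sign(lfc_DH) ==
  sign(lfc_WT)`, using the sign of the fold change *regardless of its
  significance*, computed over genes with both signs nonzero. Genes with
  an `NA` fold change in either contrast are excluded and counted.
* `amplitude_ratio`: `mean(|lfc_DH|) / mean(|lfc_WT|)` over the cluster.
  The ratio of means is used rather than the mean of per-gene ratios,
  which explodes whenever a WT fold change is near zero - and the whole
  point of this cluster is that its WT fold changes are small.

Heatmap support uses per-gene z-scores, average-linkage clustering with
`1 - Pearson` row distances and Euclidean column distances (common
defaults, fixed for reproducibility; `hclust` breaks ties
deterministically). Sample PCA is gene-centered on the most variable
genes. No significance test is attached to PCA displacement.

## Enrichment

`gsea_es()` implements the classic weighted running-sum statistic (weight
exponent 1; the extremum of largest magnitude, first occurrence on ties).
If a set covers the whole ranked universe there are no decrement steps and
the score is the maximum prefix of the increments-only walk, i.e. 1.
Significance comes from sign-matched random-set permutation with the
plus-one convention, so p-values are never exactly zero; the normalized
score divides by the mean `|ES|` of same-sign permutations. This is a
deterministic, desk-scale stand-in for the adaptive multilevel scheme of
the reference tool; p-values below `1/(n_perm + 1)` are not resolvable.
Over-representation uses the upper-tail hypergeometric distribution via
`phyper`, with an exhaustive closed-form cross-check in the tests.
"Top-N up-regulated" curation ranks positive-LFC genes by Wald statistic
by default (`lfc` and `padj` orderings available) because the criterion
used by the source of that practice is unstated.

## Interactome calling

Filters run in a fixed order, and twice-applied filtering is a no-op:

1. any detection in an empty-vector control sample removes the protein
   (strictest reading of the exclusion rule);
2. proteins detected in exactly one non-control sample are removed;
3. missing values are imputed deterministically as the global minimum
   observed log2 intensity minus 1 - imputed values sit strictly below
   all observed ones, runs are reproducible, and zero-vs-missing
   ambiguity never arises because missingness is explicit `NA`.

Exclusive DH binders need at least `min_dh_detect = 2` of the DH
replicates and zero WT detections (the "high-confidence" gate is not
defined by the source; 2-of-3 is exposed as an option). D463N detections
do not veto exclusivity by default. Preferential binders have
post-imputation `mean(DH) - mean(WT) > 0.5` (strict inequality) *or* are
exclusive - exclusivity always implies preference. Differential abundance
uses a two-sided Welch t-test with BH adjustment, the de facto standard
for triplicate label-free comparisons; proteins fully imputed on both
sides are excluded as information-free.

## Conformer classification

Residue indices are 0-based with inclusive bounds; X indexes matrix rows.
Region 1 is X in [0, 20] x Y in [350, 650] (pseudosubstrate against the
kinase domain), region 2 is X in [200, 250] x Y in [350, 650] (C2 against
the kinase domain). A model is PS-in when `mean(region1) < mean(region2)`,
PS-out when greater, and `ambiguous` on exact equality, since the decision
rule is only defined for strict inequalities. The call is invariant under
any global additive offset of the matrix. PAE is asymmetric as stored and
is used as stored; `symmetrize = TRUE` averages with the transpose for
data sources known to emit one triangle. Whether X is the "scored" or the
"aligned" axis differs between prediction tools; both regions here share
the same Y range, so the default regions are robust to that choice on
block-structured matrices, and the regions are fully configurable.

## The synthetic generators: what they emulate, what they do not

**Counts.** NB counts for four conditions with the study's replicate
structure (parental/DH/DN n = 3, WT n = 2). Gene classes: `null`;
`shared` (WT effect `beta ~ N(0, beta_sd)`, DH effect `alpha_amp * beta`);
`dh_only` (same construction at half the effect scale, so WT displacement
is real but mostly sub-threshold at n = 2 - a zero WT effect would
contradict the direction-concordance observation); `dn_specific`; and
`inactive_shared` (DH and DN move together, emulating the small
kinase-activity-dependent gene class). Baselines are log-normal
(`2^N(7, 2)`), dispersions Gamma(2, 0.025) (mean 0.05, a typical
cell-line scale), and batch shifts are drawn per gene per replicate index
and shared across conditions, so batch correction has something real to
remove. The truth table enforces `|lfc_DH| = alpha_amp * |lfc_WT|` with
equal signs exactly, which is what makes end-to-end amplitude recovery a
sharp test. Not emulated: library-size variation, gene-gene correlation,
GC/length effects, outlier counts.

**LFQ tables.** Baseline log2 intensities `N(25, 2)`, measurement noise
sd 0.3, and intensity-dependent dropout
`plogis(0.8 * (21 - x))` - roughly 9% of bait-sample cells at these
settings, a realistic missingness level for label-free data. One control
replicate is exempt from dropout for contaminants so that the
contaminant-definition invariant (recoverable from at least one control)
holds by construction. Exclusive binders are structurally absent outside
DH; preferential binders carry a true log2 enrichment drawn uniformly
from [0.5, 2.0]. Because that range starts exactly at the call threshold,
per-seed recovery of preferential binders is intentionally a boundary
exercise; the tests therefore check recovery pooled over five seeds. Not
emulated: peptide-level inference, shared peptides, batch drift between
runs.

**PAE ensembles.** Block-structured matrices (672 residues by default):
pseudosubstrate-kinase and C2-kinase blocks at `contact_pae = 5` or
`noncontact_pae = 25` depending on the conformer, everything else at
`within_domain_pae = 8`, Gaussian noise, entries clipped to [0, 31.75],
pTM `N(0.75, 0.05)` clipped to [0, 1]. With noise sd 2 the separation of
the two block means (21 x 301 and 51 x 301 cells) is enormous, so
classification accuracy is expected to be exact; the mixture-recovery
test is really a bookkeeping test of ensemble summarization.

Passing tests on these generators show the *estimators* recover known
truth under the stated noise models; they cannot show robustness to the
real-data pathologies listed above as not emulated.

## Pipeline, seeding, determinism

`run_pipeline()` executes simulate &rarr; DE &rarr; patterns &rarr;
GSEA, plus the interactome and conformer tracks, from one validated YAML
configuration (unknown keys are rejected by name). Every stochastic stage
derives its seed from the global seed and the stage name
(`stage_seed()`), so adding or disabling one stage never perturbs the
randomness of another, and a rerun with the same configuration is
byte-identical - the test suite checks output checksums. Reports contain
only values recomputable from the written stage outputs and no
timestamps.

## Problem sizes used by the test suite

Chosen as the smallest scales at which the statistical properties are
stable: amplitude/concordance recovery at 5,000 genes across five seeds;
null calibration at 10,000 genes, 5 vs 5; GSEA calibration with 200
random sets at 2,000 permutations; interactome recovery at the default
231-protein design across five seeds; conformer ensembles of 10-50
models. The bundled demo configuration (1,200 genes) exists for quick
inspection, not inference.

## Known limitations

* The dispersion model is intentionally simpler than full empirical-Bayes
  machinery; very small designs lean heavily on the trend.
* Permutation GSEA cannot resolve p-values below `1/(n_perm + 1)`.
* Deterministic minimum-imputation compresses variance for
  mostly-missing proteins; the Welch test on such proteins is
  conservative at best. A stochastic imputation mode is out of scope.
* The conformer classifier assumes the two regions capture the relevant
  domain contacts; for proteins with different architecture the regions
  must be re-specified.
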