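---
title: "Models and methods behind sexbiasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sexbiasr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexbiasr)
```

sexbiasr characterises sex-biased gene expression (SBG: sex-biased gene;
FBG/MBG: female-/male-biased gene) from bulk RNA-seq count matrices across
species with different sex-chromosome systems, and asks two evolutionary
questions on top of the per-species results: whether expression divergence
between a focal and a related species carries a signature of directional
selection (the Δx statistic), and how concordant two species' sex-bias
profiles are (rank–rank hypergeometric overlap, RRHO). This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where a choice was genuinely open. It states no result
that the package's tests do not themselves compute.

## Differential expression model

Counts for gene *g* in sample *j* are modelled as negative binomial with
mean `s_j * q_gj` and dispersion `alpha_g` (`var = mu + alpha * mu^2`).
`log q_gj` is a linear function of sex (plus tissue in the combined
design), fitted by IRLS with the log size factor as offset. The sex
contrast is male minus female, so a positive log2 fold change (LFC) means
male-biased. Significance comes from a two-sided Wald test on the sex
coefficient with Benjamini–Hochberg correction; a gene with adjusted
p < `alpha` (default 0.05) is an SBG, FBG if LFC < 0 and MBG if LFC > 0.
Deliberately, *no* LFC cutoff enters classification: sexually antagonistic
selection is expected to produce many small expression differences, and a
fold-change filter would discard exactly those.

Two designs are supported per species: `tissue_combined` (`~ tissue + sex`,
all organs jointly; requires at least two tissues) and `tissue_specific`
(`~ sex` within one tissue). Tissue-specific runs reuse the gene set that
passed filtering on the full species matrix, so the per-tissue results are
comparable across tissues of the same species.

**Filtering.** A gene is kept when it has at least `min_count = 5` reads in
strictly more than `min_samples_exclusive = 3` samples (i.e., four or
more). The boundary is deliberate: `[5,5,5,5,0,...]` passes,
`[5,5,5,0,...]` does not.

**Size factors.** Median-of-ratios: per sample, the median over reference
genes (positive counts in every sample) of the count divided by the gene's
geometric mean across samples. Identical samples get unit factors, and
normalised counts are invariant under global rescaling of any sample.

**Dispersion.** The per-gene method-of-moments estimate
`(var - mean)/mean^2` of normalised counts, computed within design cells
and pooled by residual degrees of freedom, is unbiased on average but far
too noisy at two to three replicates per cell: plugging it into a
fixed-dispersion Wald test inflates the false-positive rate several-fold.
The default (`method = "trend"`) therefore fits the parametric trend
`alpha(mu) = a0 + a1/mu` across genes (Gamma GLM, identity link, with a
trimmed-mean fallback when the fit fails) and uses the fitted value for
every gene, pooling the moment information across the whole matrix. With
the trend the package's null simulations give near-uniform raw p-values
(mean Kolmogorov–Smirnov D ≈ 0.03 at 2,000 genes) and essentially zero SBG
calls at FDR 0.05. `method = "shrunk"` (log-scale compromise with
`prior_df = 10`) and `method = "gene-wise"` remain available; the gene-wise
route is what the parameter-recovery tests check (median within ±50% of a
true alpha of 0.2 at 30 samples). The cost of the trend is that genuinely
dispersion-heterogeneous genes are mis-weighted - a known limitation shared
with common/trended-dispersion approaches; there is no empirical-Bayes MAP
shrinkage, outlier replacement, or independent filtering here.

Genes whose IRLS fit fails to converge receive `NA` p-values and are
excluded from the BH family, which must be defined somehow; this is the
most conservative family that still tests every fitted gene.

## Chromosome landscape

Genes are classed per species as `sex_chromosome` (any declared sex-linked
linkage group), `autosome`, or `excluded` (mitochondrial or on unplaced
scaffolds). Excluded genes never enter sex-chromosome-vs-autosome
contrasts; species with unknown heterogamety yield no sex-chromosome labels
at all and therefore simply cannot enter such contrasts. Enrichment of
SBGs on a chromosome is a two-sided Fisher exact test of (SBG vs non-SBG) ×
(on chromosome vs autosomes); the autosomal background excludes every
declared sex chromosome, so for a species with a fused pair (say LG05 +
LG13) each is contrasted against autosomes excluding the other. All Fisher
tests are two-sided - the conservative default since directionality
conventions vary. Cross-species sharing tests intersect the genes tested in
both species first; bias-intensity comparisons use Wilcoxon–Mann–Whitney
for two groups and Kruskal–Wallis for three or more, on SBG LFCs.
Per-chromosome SBG proportions use expressed (tested, non-excluded) genes
as denominator - the natural choice given that untested genes carry no bias
information; this is configurable in spirit by pre-filtering the input.

Feminisation metrics per chromosome group: median LFC of SBGs (negative =
feminised), mean |LFC| of FBGs and MBGs separately, and the FBG:MBG count
ratio, always with group sizes so that small groups are recognisable.

## The Δx expression-divergence statistic

For each gene, on log2(TPM + pseudocount) replicate values:

* `d = (mean_focal - mean_related) / mean_focal` - relative divergence.
  The verbal definition of `d` is ambiguous about parenthesisation; this
  reading is the one consistent with both means being *relative* gene
  expression, and is the package's documented choice.
* `r = (max_focal - min_focal) / mean_focal` - relative within-species
  range, a noise yardstick.
* `f = sqrt((m*N - 1)/(m*N - m))` - sample-size correction with `m` the
  focal replicate count and `N = 3` the reference (most common) sample
  size. `f(3,3) = sqrt(8/6) ≈ 1.1547`; the factor equals 1 at `m = 1` and
  grows slowly towards `sqrt(N/(N-1))` as `m` increases, compensating the
  growth of the raw range with sample size.
* `Δx = d / (f * r)`; `|Δx| > 1` flags putative directional selection, up
  if `Δx > 1`, down if `Δx < -1`.

Degenerate inputs are kept, not dropped: `d = 0` yields `Δx = 0` (class
"none") even when `r = 0`; `r = 0` with `d ≠ 0`, or a zero focal mean,
yields class "undefined" with `Δx = NA`. Undefined genes are excluded from
both cells of selection-enrichment contingency tables by default
(`undefined = "exclude"`), with `"not_selected"` available - preserving the
gene universe is an explicit policy decision, not an accident of NA
handling.

Δx is computed per tissue × sex by default, so the focal sample size
matches the per-sex replicate count that the reference `N = 3` refers to
(gonads are sex-specific organs anyway); `by_sex = FALSE` pools sexes. The
TPM pseudocount (default 1) is configurable since the original procedure
leaves it unstated. Two asymmetries of the statistic are worth knowing:
TPM renormalisation means that shifting part of the transcriptome up
pushes unshifted genes slightly down (compositional coupling), and the
pseudocount compresses downward shifts of lowly expressed genes, so
downregulation is systematically harder to call than upregulation near the
detection floor. The recovery tests therefore condition on genes with
within-species CV ≤ 0.1, where both directions are called reliably.

## RRHO concordance

Each species' profile is summarised per gene by the degree of differential
expression `DDE = -log10(p) * sign(LFC)` (negative = female-biased), with p
floored at 1e-300 and `DDE = 0` when `LFC = 0`. Adjusted p-values are the
default source, matching the upstream analysis; raw p-values are available
and are the better choice for the sign-concordance summary, because
adjusted p-values saturate at 1 for most unbiased genes and would leave
their DDE sign undefined. Genes are ranked (rank 1 = most female-biased,
ties broken by gene id for determinism) in both species, restricted to
shared genes, and binned with stepsize `ceil(sqrt(n))` by default. For
every threshold pair the overlap of the two top lists is scored with the
hypergeometric distribution; the stored cell p-value is the smaller of the
over- and under-enrichment tails and the signed score is `-log10(p)`,
positive for over-enrichment. Benjamini–Yekutieli correction is applied
over all grid cells - the cells are strongly dependent, which is exactly
the regime BY is valid in. The map is invariant under strictly monotone
transforms of DDE, as a rank-based method must be.

"Concordantly expressed" has no universal operational definition under
RRHO; the package reports two: the proportion of shared genes whose DDE
signs agree (among genes with both signs nonzero), and a quadrant-based
readout (strongest BY-corrected signal in the two concordant corner
quadrants). Neither is privileged.

## The synthetic-data generator

The simulator emulates the targeted study design: per species, five
tissues (gonad, brain, gills, liver, lower pharyngeal jaw) × two sexes ×
three replicates, with genes on 22 linkage groups plus a mitochondrial
contig and unplaced scaffolds. Counts are negative binomial with
`var = mu + alpha * mu^2`. Per-gene log2 baselines are Normal(5, 2);
per-gene, per-tissue effects Normal(0, 2) (the `tissue_effect_sd` field
exists so that QC PCA has true tissue structure to find); library-size
factors are log-uniform on [0.5, 2]; gene lengths uniform on 300–10,000 bp
and shared across species (orthologs have identical ids and lengths by
construction). The sex effect is injected symmetrically: +LFC/2 in males,
−LFC/2 in females, so the male/female log2 mean ratio equals the recorded
truth and total expression stays orthogonal to bias. A gene becomes a true
SBG with probability 0.02 on autosomes and 0.10 on declared sex
chromosomes; on a ZW sex chromosome the bias is female with probability
0.8 (feminisation), on XY with probability 0.2 (the mirrored
masculinisation - one parameter serves both systems), 0.5 on autosomes.
|LFC| is `abs(Normal(2, 0.5))` log2 units. These fractions and magnitudes
are free parameters of the generator, not estimates of any real species'
biology: real dispersion and effect-size distributions are unknown here,
real bias is strongly tissue-dependent (the generator applies a gene's
bias in every tissue), and there are no batch effects, isoform structure
or mapping biases. Passing recovery tests therefore demonstrates that the
estimators recover the generating model, not that they would behave
identically on real data.

Each species consumes its own RNG stream (sub-seeds drawn once from the
master seed, in species order), so adding a species never perturbs
existing species' data. The focal/related pair generator shares the
sex-bias truth between the two species (optionally only partially, via
`sbg_shared_fraction`) and adds divergence shifts of ±2 log2 units to a
configurable fraction of genes - optionally at a higher rate among SBGs -
which is what the directional-selection recovery tests exploit.

`replicates_per_sex` must be at least 2 because the relative range `r` of
a single replicate is undefined.

## Numerical choices and problem sizes

IRLS runs to relative tolerance 1e-8 with at most 100 iterations;
dispersions are floored at 1e-8 (near-Poisson) and the NB family is
parameterised via `theta = 1/alpha`. Wald standard errors come from the
Fisher information at convergence with dispersion treated as known.
p-value floors (1e-300) precede every log10. Fisher exact p-values are
validated against exhaustive hypergeometric enumeration built only from
log-binomial coefficients; the Δx chain is validated against a one-line
independent recomputation to 1e-12.

The test suite's simulations use 250–2,000 genes, two to three tissues and
20–50 seeds per recovery claim - sizes chosen so each claim has clear
binomial resolution while the whole suite stays quick; the acceptance
script analyses 3,000 genes across two species. Scaling genes up changes
none of the algorithms, only runtime, since every estimator is per-gene or
a single pass across genes.

## Known limitations

* The DE model omits empirical-Bayes dispersion shrinkage, outlier
  handling and independent filtering; counts of borderline SBGs will not
  match tools that include them.
* Trend-based dispersion mis-serves genes whose true dispersion departs
  strongly from the mean trend.
* Δx inherits the compositional and pseudocount asymmetries described
  above and does not separate selection from drift beyond the |Δx| > 1
  convention.
* The generator's bias-in-every-tissue simplification makes the
  tissue-combined design slightly more powerful on synthetic data than it
  would be on real, strongly gonad-dominated bias.
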