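---
title: "Methods: factorial NB differential expression, gene-group classification, enrichment and voxel mapping"
author: "mntox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial NB differential expression, gene-group classification, enrichment and voxel mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mntox)
```

This vignette documents the statistical machinery of `mntox`: the models
it fits, the defaults it ships, the numerical choices behind them, what
its synthetic-data generators do and do not emulate, and the known
limitations. It states no empirical result beyond what the package's
test suite and `scripts/acceptance.R` compute.

## The factorial design

The package targets a two-by-two design: a genotype factor (homozygous
*mutant* versus pooled wild-type/heterozygous *siblings*) crossed with a
treatment factor (metal-*exposed* versus *unexposed*), with individual
animals as replicates. Pooling wild-type and heterozygous individuals is
appropriate when a recessive allele shows no heterozygous expression
signature; `analysis_group()` encodes exactly this rule. The model
matrix has four columns — intercept, genotype, treatment, interaction —
with reference levels sibling and unexposed, so the four natural
comparisons are single coefficients or short sums of them
(`standard_contrasts()`).

## The NB differential-expression engine

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$ and log link with offset $\log s_j$.

**Normalisation.** `size_factors()` implements median-of-ratios: each
sample's factor is the median, over genes positive in every sample, of
the count divided by the gene's geometric mean, rescaled so the size
factors have geometric mean 1. The median is taken on the raw ratio
scale. When no gene is positive everywhere (heavily zero-inflated
matrices), an explicit `pseudo_reference = TRUE` falls back to per-gene
geometric means over positive samples only, rather than guessing
silently.

**Fitting.** Because the four-coefficient model with one intercept per
design cell is saturated, the per-gene maximum-likelihood problem
decomposes into four one-dimensional problems — one fitted mean per
condition — which the engine solves by Fisher scoring on the log scale,
vectorised across all genes simultaneously. Coefficients are the fixed
linear map of the cell log-means, reported in log2 units; the covariance
is the inverse Fisher information mapped through the same linear
transformation. A condition whose counts are all zero makes the
coefficient non-identifiable; such genes are flagged as non-converged
and excluded from testing, never dropped silently. Step sizes are capped
at 3 natural-log units per iteration and the fitted mean is floored at
$10^{-8}$ for numerical safety.

**Dispersion.** `estimate_dispersions()` proceeds in three stages
familiar from count-GLM practice: (i) per-gene maximum-likelihood
$\hat\alpha$ given the fitted means, maximised on the log scale with a
Cox–Reid adjustment ($-\tfrac12\log\det X^\top W X$, which is a sum of
per-cell log-information terms here) to correct the downward bias of
plain profile likelihood; (ii) a mean–dispersion trend
$\alpha_{tr}(\mu) = a_0 + a_1/\mu$ fitted by a Gamma GLM with identity
link over genes with usable estimates
($\hat\alpha \in (10^{-7}, 10)$, mean normalised count $\ge 1$), with a
median fallback if the GLM fails or returns a non-positive asymptote;
and (iii) per-gene posterior modes shrinking $\log\hat\alpha$ towards
$\log\alpha_{tr}(\bar\mu_i)$ under a normal prior whose variance is the
robust spread (squared scaled MAD) of the log residuals minus the
approximate sampling variance $\psi'((m-p)/2)$, floored at 0.25. The
optimisation bounds $[10^{-8}, 30]$ cover everything from
quasi-Poisson to extremely noisy genes.

**Testing.** `wald_contrast()` computes $c^\top\hat\beta$, its standard
error from the coefficient covariance, a two-sided standard-normal
p-value, and BH adjustment across the converged genes of that contrast
(`adjust_bh()` wraps `stats::p.adjust`, excluding missing values from
the number of tests). The default significance threshold throughout is
an adjusted p of 0.05.

One property worth stating precisely: multiplying all counts of one
sample by a constant moves that sample's size factor by exactly the same
constant, but leaves LFC estimates only *approximately* unchanged
(differences of order $10^{-2}$ at $\alpha = 0.05$), because the NB
score weights each sample by its fitted mean, so a rescaled sample
re-weights its condition. This is intrinsic to exact ML with offsets and
not a numerical artefact.

## Sample QC

The study design this package follows excluded one sample after visual
inspection of a PCA. `pca_outlier_qc()` formalises that judgement:
counts are transformed to $\log_2(\text{normalised count} + 1)$, samples
are projected on the first two principal components (each PC's sign
fixed so its largest-magnitude loading is positive, for determinism),
and a sample is flagged when its distance from its condition's *median*
centroid exceeds `k_mad` (default 5) times the MAD of all
within-condition distances. The median centroid matters: a mean centroid
is dragged by the very outlier being sought, which inflates its
condition-mates' distances. Note that a sample whose counts are globally
rescaled is *not* an outlier under this rule — size-factor normalisation
absorbs uniform scaling exactly, which is the desired behaviour; the
rule detects samples whose expression *profile* deviates. The transform
and the distance rule are this package's formalisation; the original
analysis stated only visual inspection.

## Gene-group classification

`classify_genes()` applies the three-group logic at threshold `q`
(default 0.05): group 1 (toxicity) is significance in exposed-vs-unexposed
siblings; group 3 (mutant effect) is significance in unexposed-mutant
vs unexposed-sibling; group 2 (increased sensitivity) is significance in
exposed-mutant vs unexposed-sibling *and* no significance in either
single comparison. Groups are deliberately not mutually exclusive.
Missing adjusted p-values (non-converged genes) count as not
significant.

`split_sensitivity()` calls a group-2 gene *synergistic* when the
interaction coefficient is itself significant and has the same sign as
the total exposed-mutant effect — the combined single effects fall
significantly short of the observed change — and *additive* otherwise.
A significant interaction of *opposite* sign is not synergy by this
definition; such genes stay additive in `sensitivity_mode` and are
flagged in a separate `antagonistic_interaction` column so they are
visible rather than misfiled.

`rescue_report()` calls a group-3 gene *rescued* when it is no longer
significant in the exposed-mutant comparison — the expression pattern
expected if the mutation causes a local metal deficiency that exogenous
metal corrects — and *persistent* otherwise; persistent genes that also
sit in group 1 are marked `most_sensitive_target`. Classification is a
pure function of the four result tables and `q`; re-reading saved tables
reproduces it bit-for-bit, which the test suite asserts.

## Ontology enrichment

`load_obo()` parses `[Term]` stanzas of OBO 1.2/1.4 files, keeping
`is_a` edges only (zebrafish-anatomy- and GO-style ontologies; `part_of`
support would be a configuration extension, not a different algorithm).
Obsolete terms are skipped and counted; cycles are a hard error naming
the offending terms. `propagate_annotations()` applies the true-path
rule (a gene annotated to a term is annotated to all its ancestors);
propagation is idempotent and tested against a brute-force ancestor
walk.

`term_for_term()` is the right-sided (enrichment-only) hypergeometric
test of each term against the whole population with Holm–Bonferroni
correction; terms with no study gene are not tested, matching
"enrichment only", and ties in the Holm ordering are broken by term id
for determinism. Corrected values above 0.05 are kept in the output with
a `discarded` flag rather than removed. `parent_child_union()`
conditions each term's test on the genes annotated to the union of its
`is_a` parents — the draw is the study genes in that union, successes
are genes of the term itself — with Bonferroni correction; roots are
skipped. When a term's annotation set equals its parent union the test
is degenerate and returns p = 1. The enrichment population defaults to
all annotated genes; analyses restricting the population to detected
genes can pass it explicitly.

## Voxel-wise activity mapping

The imaging chain emulates registered whole-brain stacks of an
immediate-early-gene signal for two groups: `median_filter3d()` (cube
neighbourhood, reflection at edges, default radius 1, i.e. 3×3×3 — the
source analysis did not state a kernel size), `permutation_test()`
(statistic: difference of group means per voxel; p-value: proportion of
group-label assignments, observed labelling included, with at least the
observed absolute statistic; all $\binom{n_A+n_B}{n_A}$ assignments
enumerated when there are at most 10,000, otherwise Monte-Carlo with a
mandatory seed and the identity always included), `fdr_mask()` (BH
across voxels, passing voxels split by statistic sign into enhanced and
suppressed masks) and `region_summary()` (voxel, enhanced and suppressed
counts and fractions per atlas region, sorted by the larger fraction).

Two numerical facts shape sensible defaults here. First, with $n=6$ per
group the exact two-sided permutation p-value cannot go below
$2/\binom{12}{6} = 1/462 \approx 0.0022$, because the label-complement
assignment always ties the observed statistic in absolute value.
Second, the upstream study states its threshold two ways — "an FDR
threshold of 0.05%" and "a 99.5% significance threshold" — which are
numerically different (0.0005 versus 0.005). Both are supported;
`fdr_mask()` defaults to `q = 0.0005`. At that setting a 6-versus-6
exact test can never reject (the BH bound $q \cdot k/m$ is always below
the p-value floor), so planted-effect recovery demonstrations and the
planted acceptance checks use the `q = 0.005` reading, under which
recovery requires the affected voxels to be a substantial fraction of
the volume ($\ge 0.43$ at the floor). The null-simulation FDR check uses
the stricter default. Larger groups or Monte-Carlo designs with more
subjects escape the floor and make `q = 0.0005` operational.

## Synthetic data with ground truth

`simulate_counts()` inverts the fitted model: per-gene coefficients are
planted by truth class, counts drawn as NB with variance
$\mu + \alpha\mu^2$. Defaults define the reference study conditions:
four conditions × 8 individuals (sibling slots alternate wild-type and
heterozygous, emulating a balanced pick from a heterozygous incross;
per-condition counts were not published, so this is the package's
choice of a realistic single-clutch design), 5,000 genes, baseline
$\log_2$ expression Normal(7, 1.5), dispersion log-normal with median
0.05 and log-sd 0.5 (typical for well-replicated larval RNA counts),
true size factors log-uniform on $[0.5, 2]$ to exercise normalisation,
5% of genes per effect class and planted effects of 2 log2 units.

The additive sensitivity class needs care: its defining property is that
neither single effect is detectable alone but their sum is. The
generator calibrates a *detection scale* $d$ empirically once per
configuration: a pilot dataset with the same configuration (additive
slots as nulls) is run through the package's own engine; the realised
BH significance threshold on the Wald statistic, $z^\*$, times the
median coefficient standard error is the LFC at which a typical gene is
detected with probability one half. Additive genes then receive single
effects of $0.7d$ each (both below $d$) and a combined effect of
$1.4d$ (above it). Genes of the rescued class receive an interaction
exactly cancelling their genotype effect, so their exposed-mutant total
is zero by construction; synergistic genes carry a pure interaction, so
its sign matches the total effect as the definition requires.

What the generators do *not* emulate: positional 3′-end artefacts,
polyA mispriming, batch structure, correlated genes, registration error
or spatially correlated imaging noise (volume noise is i.i.d. Gaussian;
a real registered stack has smooth noise and partial-volume edges), or
amplification-efficiency drift in qPCR. Passing the recovery tests
therefore demonstrates correctness of the statistical machinery under
its own model assumptions, not robustness to every artefact of real
data.

## Validation sizes and runtimes

The acceptance checks run at the reference conditions: 5,000 all-null
genes for Wald calibration; 2,500 genes (500 per planted coefficient
class) for effect-recovery bias, measured separately for up- and
down-regulated genes so symmetric errors cannot cancel; the full default
configuration for six-class recall; 20 seeds of 8×8×8 null volumes and
one 10×10×12 planted volume (two effect slabs of ten noise-SDs, six
subjects per group) for the imaging chain; and exhaustive enumeration
oracles for every closed-form primitive. These sizes keep the whole
validation suite around two minutes on a single CPU while leaving
Monte-Carlo error well below the asserted margins.

## Known limitations

* The engine fits only the 2×2 factorial with intercept; no continuous
  covariates, batch terms or time courses.
* No outlier-count replacement or independent filtering; dispersion
  shrinkage has no outlier-gene escape hatch, so a few genuinely
  high-dispersion genes are over-shrunk.
* Exact replication of any particular published gene list is out of
  scope: it would require the original raw counts, annotation version
  and upstream tag filtering.
* The OBO parser covers the subset of the format the enrichment methods
  need (ids, names, `is_a`, obsolescence), not the full standard.
* Permutation p-values are valid for exchangeable subjects; registered
  volumes with group-specific smoothness violate that silently.
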