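---
title: "Smoking-associated DNA methylation: cell-mixture correction, EWAS, and weighted-network module discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoking-associated DNA methylation: cell-mixture correction, EWAS, and weighted-network module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokeMethNet)
```

## The analysis this package implements

smokeMethNet implements a complete analysis chain for asking how chronic
smoking reshapes blood DNA methylation, at three levels of organisation:

1. **Single CpG probes.** Per-probe linear models of the methylation
   fraction (beta value) on smoking status, adjusted for technical batches
   (array slide, processing plate) and for blood cell composition, with
   Benjamini–Hochberg (BH) control of the false discovery rate across the
   whole array.
2. **Gene promoters.** All beta values of a gene's promoter probes,
   flattened into one vector per smoking group and compared by an unpaired
   t-test, BH-corrected across genes — giving each gene an adjusted
   p-value $p'$.
3. **Protein networks.** A protein–protein interaction network whose edges
   are weighted by the significance of their endpoint genes,
   $$w_{ij} = \frac{\log(p'_i \, p'_j)}{\log(p'^2_{\min})},$$
   searched greedily for connected sub-networks that concentrate
   differential methylation, with permutation-based significance; each
   discovered module (and the genome-wide changed-gene set) is then tested
   for Gene Ontology over-representation with the hypergeometric tail.

Every input the chain needs — cohort beta matrix, sample sheet, probe
annotation, purified-cell reference panel, PPI edge list, GO sets — can be
simulated by the package's generators with known ground truth, so each
stage is testable end to end without downloads.

## Beta values, masking, and input handling

A beta value is the methylated-probe intensity divided by total intensity
at a CpG: a methylation fraction in $[0,1]$. Values whose detection
p-value exceeds 0.05 are masked on input (strictly greater than: a value
at exactly 0.05 is kept). Downstream models are complete-case per probe;
probes with fewer than 10 unmasked samples are skipped with a recorded
reason. Analyses run on the beta scale, which is what the ranked outputs
report; a logit (M-value) transform is available behind a flag in
`fit_probe_models()` for users who prefer variance-stabilised modelling.

## Cell-mixture surrogates

Whole-blood methylation differences can reflect cell-type composition
rather than exposure. The correction here is reference-based but uses PCA
surrogates rather than full proportion estimation:

* `derive_celltype_sites()` fits, per probe, a one-way fixed-effects model
  of beta on cell type across a purified-cell panel (five sorted leukocyte
  types by default, CD4+ T, CD8+ T, CD14+ monocytes, CD19+ B, CD56+ NK),
  takes the overall F-test p, and BH-corrects across probes.
* `compute_surrogates()` takes the cohort's betas at the **top 100** sites
  (ranked by raw p; ties at the boundary are all kept), runs an unscaled,
  column-centred PCA on the samples-by-sites matrix, and returns the first
  **5** component scores per sample with their explained-variance
  fractions.

Two design points were genuinely open and are decided here: the PCA runs
on the *cohort's* betas at the reference-derived sites, because only that
yields one covariate row per cohort sample, which the downstream model
needs; and the PCA is on the covariance (unscaled) matrix since all
features share the beta scale. Ranking is by p-value rather than effect
size. Component signs are fixed by making each component's
largest-magnitude loading positive, so results do not depend on LAPACK
sign conventions.

## The probe-level EWAS

For each probe, `fit_probe_models()` fits OLS of beta on
`smoker + slide + plate + PC1..PC5` with treatment contrasts (reference
level = first category in lexical order) and reports the smoking
coefficient's two-sided t-test. Smoking is coded 1 = smoker, so a negative
coefficient means smokers are hypomethylated. BH adjustment uses
m = the number of probes actually fitted. Rank-deficient designs (e.g.
smoking perfectly confounded with a slide) and zero-variance probes are
skipped and counted, never silently dropped.

`bh_adjust()` supports a *top-slice* family: when only the k smallest of m
raw p-values are available (as in a published top-30 table from a
485,577-probe array), the step-up rule is still exact for those k entries
because adjusted values are non-decreasing in rank; the caller asserts the
slice really contains the smallest raw p's.

## Promoter-level testing and the weighted network

"Promoter" defaults to the TSS1500 and TSS200 manifest categories; the set
is configurable, and widening it can only grow each gene's probe set. A
probe annotated to several genes contributes to all of them — no signal is
discarded. The gene test flattens all unmasked (probe x sample) values
into one vector per group and applies the classical pooled-variance
unpaired t-test (Welch is available behind a flag, as is a per-sample-mean
mode that collapses each sample's promoter probes before testing; the two
modes differ materially in degrees of freedom).

**A calibration caveat that matters.** The flattened test treats all
probe-by-sample values as exchangeable. When a gene's promoter probes have
identical baselines this is exact, and on such an i.i.d. null cohort the
raw p-values are uniform. When probes differ in baseline, the
between-probe spread inflates the variance estimate and the test becomes
conservative; when samples carry shared structure (batch, cell mixture)
it can become anti-conservative, because gene-level testing — unlike the
probe-level model — carries no covariates. This is an inherent property of
the flattened construction and is why the probe-level model, not the gene
test, is the package's inferential workhorse; the gene p' values feed the
network stage, where only their ranking and magnitude matter.

Edge weights use the natural log (any base cancels in the ratio). The
weight is 1 exactly when both endpoints sit at the table minimum and 0
when both are at $p' = 1$; p-values are floored at 1e-300 before logs.
Unmapped interactions (an endpoint absent from the gene table) are
dropped with a logged count.

## Module discovery

The module score is a **parametric local modularity**: for a connected
node set $S$,
$$Q_\gamma(S) = \frac{W_{in}}{W_{in} + W_{bnd}},$$
where $W_{in}$ sums $w^\gamma$ over edges inside $S$ and $W_{bnd}$ over
edges crossing its boundary. $\gamma$ (default 1) controls how strongly
edge weights dominate topology; $\gamma = 0$ reduces to unweighted edge
counts, which is what the test-suite oracle checks. The score is isolated
in one function (`local_modularity()`) so an alternative definition is a
one-function swap.

`greedy_expand()` grows a module from a seed edge, each step adding the
neighbour with the largest score increase, ties broken by higher node
$-\log_{10} p'$ and then lexical symbol. A node is only added if it
improves the score by at least `min_improve` (default 0.025). The
threshold exists because genuine module growth raises the boundary ratio
in large steps, while near-zero positive increments come from weak
peripheral nodes whose tiny strength happens to point inward; accepting
those dilutes module membership without materially changing the score.

`find_modules()` expands the top `max_seeds` edges by weight, then scores
each candidate against a null built by permuting the node p' values over
nodes, rebuilding all edge weights from the closed-form equation
(p'_min is permutation-invariant), and re-running the identical
seed-selection-plus-expansion sweep `n_null` times. The empirical p of an
observed module is the add-one-smoothed fraction of null sweeps whose best
module *of the same size* scores at least as high — stratified by size
because the boundary-ratio score distribution depends strongly on module
size. Because each occupied size stratum is a separate test, acceptance
uses a Bonferroni-adjusted threshold `alpha / n_strata` (disable with
`fwer_correct = FALSE`); without it, a null network yields a spurious
"significant" module in roughly `alpha x n_strata` of runs. Accepted
modules are greedily deduplicated by descending score at a Jaccard overlap
cap of 0.5. A degree-preserving edge-rewiring null is a documented
alternative but the p'-permutation null is the default, since it preserves
the topology and the p' distribution exactly and asks precisely the
question of interest: do the low-p' genes cluster on the network?

## GO over-representation

`enrich()` tests each term by the hypergeometric upper tail on the overlap
between a query set and the term's members, both intersected with the
universe first, BH-corrected across terms. Two modes mirror the two uses:
genome-wide (query = genes owning an FDR-significant probe, universe =
genes owning any fitted probe) and per-module (query = module members,
universe = all genes in the weighted network; the universe choice is
configurable). A permutation-FDR mode (resampling random queries of equal
size) is available; the flat GMT fixture carries no ontology hierarchy and
ancestor propagation is deliberately out of scope.

## What the synthetic data emulates — and what it does not

`generate_cohort()` builds each sample as a Dirichlet-weighted mixture of
per-cell-type methylation profiles (concentration (10, 10, 8, 4, 2) —
a monocyte/lymphocyte-dominant blood-like mixture, fixed by choice), plus
probe-by-slide and probe-by-plate Gaussian batch offsets, plus cell-level
noise, clipped to $[0,1]$. Baselines are bimodal over (0.05, 0.95) as on
real arrays, and probes of the same gene scatter tightly (sd 0.05) around
a shared gene anchor, as promoter CpGs do. Defaults mirror the study
design the pipeline targets: 50 smokers, 61 non-smokers, 12 slides, five
purified cell types with six replicates each, planted beta-scale effects
of 0.03–0.15 — the range of group differences seen among top
smoking-associated probes — placed on interior-baseline probes (where an
additive shift survives clipping) disjoint from the planted cell-type
probes. Plates are assigned independently of slides so both covariates
are estimable.

`generate_ppi()` plants modules as cliques-with-dropout (connectivity
guaranteed by a spanning path) over genes drawn from the low-p' pool
(p' <= `low_p_max`), embedded in a configuration-model-style background
(Poisson degrees, default mean 8) with two bridges per module member.
The embedding is deliberate: with too few bridges a module's boundary
ratio saturates regardless of weights, so a permutation null rediscovers
it on topology alone; with one bridge per member and weak targets, the
greedy search swallows bridge targets as near-pendants. Two bridges per
member to distinct, well-connected, unremarkable-p background genes makes
module discovery hinge on the weight contrast — the property the search
is supposed to detect.

Not emulated: type I/II probe chemistry bias, age/BMI covariates,
genomic coordinates, longitudinal structure, and real PPI degree
distributions. Passing tests therefore demonstrate that the machinery
recovers planted structure under the stated noise model — not that the
biological conclusions of any particular cohort would replicate.

## Numerical and calibration choices

* Calibration checks run at 20,000 probes x 111 samples across 20 seeds
  for null behaviour, and at the default 2,000-probe cohort for effect
  recovery; module-search checks use a 300-gene network with `n_null` =
  200 and `max_seeds` = 100. These sizes were chosen so the full suite
  runs comfortably on a laptop while leaving the binomial tolerances of
  the checks meaningful; the function defaults (`n_null` = 1000,
  `max_seeds` = 500) are higher.
* The i.i.d. variant of the null cohort (no batch offsets, no cell-type
  contrast, `gene_jitter_sd = 0`) is used for uniformity checks of the
  flattened gene test, since that is the regime where its assumptions
  hold exactly; count-level null checks run under the full default
  conditions with surrogate correction, as the pipeline actually runs.
* Randomness: every generator op draws from its own stream derived from
  the master seed by `derive_seed(seed, label)` (counter-based fan-out,
  kept below 2^31), so regenerating one artifact never shifts another's
  randomness, and the global RNG state is restored after every call.
* Degenerate inputs fail loudly: beta values outside $[0,1]$ name the
  offending cell, a flat gene-p table is "unweightable", an all-constant
  surrogate-site matrix is a degenerate-input error, and a cohort where
  smoking is confounded with a batch covariate reports every probe as
  skipped rather than returning half-estimates.

## Known limitations

* The gene-level flattened t-test is miscalibrated under within-gene
  baseline heterogeneity or shared sample structure (see above); its
  output should be read as a ranking, which is all the network stage
  consumes.
* The parametric-local-modularity score is one member of a family; the
  exponent $\gamma$ and the boundary-ratio form are this package's
  definition, reconstructed to produce dense low-p' modules in the 5–25
  size range, and deliberately swappable.
* Empirical module p-values are bounded below by 1/(n_null + 1); with the
  default acceptance correction, `n_null` must exceed the number of
  occupied size strata divided by `alpha` for any module to be acceptable.
* Multi-gene probes induce dependence between gene tests; BH is applied
  regardless, as is standard practice.

## A short worked run

```{r worked, eval = FALSE}
panel <- reference_panel_spec(seed = 7)
spec <- cohort_spec(n_effect_probes = 60, seed = 7)
co <- generate_cohort(spec, panel)
ref <- generate_reference_panel(panel, n_probes = spec$n_probes)

ranking <- derive_celltype_sites(ref$betas, ref$labels)
surr <- compute_surrogates(co$betas, ranking)
ewas <- fit_probe_models(co$betas, co$sheet, surr)
summarize_counts(ewas)

gene_p <- promoter_t_tests(co$betas, co$sheet,
                           assign_promoter_probes(co$annotation),
                           per_sample_mean = TRUE)
ppi <- generate_ppi(setNames(gene_p$adjusted_p, gene_p$gene),
                    module_sizes = c(6L, 15L),
                    low_p_max = sort(gene_p$adjusted_p)[21], seed = 7)
net <- build_weighted_network(ppi$edges, gene_p)
find_modules(net, search_config(n_null = 200, max_seeds = 100, seed = 7))
```

The numbered scripts under `analysis/` run the same chain stage by stage,
writing every intermediate under `results/pipeline/` and printing the
per-stage counts (sites selected, probes significant, genes tested, edges
mapped, modules accepted) that serve as the audit trail.
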