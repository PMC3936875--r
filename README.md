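# smokeMethNet

Chronic smoking leaves a broad footprint on the DNA methylation of blood
mononuclear cells. Detecting it credibly requires more than a per-CpG
test: blood is a cell mixture (composition differences masquerade as
exposure effects), arrays carry slide- and plate-level batch structure,
and single-locus hits say little about which biological processes are
being rewired. smokeMethNet is an R package for epigenetics researchers
that implements the full analysis chain:

1. **Cell-mixture surrogates** — rank probes by a one-way cell-type
   F-test across a purified-leukocyte reference panel (BH-corrected),
   take the top 100 sites, and use the cohort's first 5 principal-component
   scores at those sites as covariates.
2. **Probe-level EWAS** — per-probe OLS of the beta value on smoking
   status with slide, plate and surrogate covariates; two-sided t-test on
   the smoking coefficient; Benjamini–Hochberg FDR across all fitted
   probes; ranked output table.
3. **Promoter-level testing** — for each gene, the beta values of its
   promoter probes compared between smokers and non-smokers by an unpaired
   t-test, BH-adjusted across genes to give each gene an adjusted p-value
   *p′*.
4. **p-value-weighted network** — a protein–protein interaction edge list
   is weighted by

   &nbsp;&nbsp;&nbsp;&nbsp;*w<sub>ij</sub>* = log(*p′<sub>i</sub>* · *p′<sub>j</sub>*) / log(*p′*<sub>min</sub><sup>2</sup>)

   which maps gene-pair significance into [0, 1].
5. **Module discovery** — greedy expansion from top-weight seed edges
   maximising a parametric local modularity
   *Q* = *W*<sub>in</sub> / (*W*<sub>in</sub> + *W*<sub>bnd</sub>), with
   empirical significance from node-permutation null networks.
6. **GO over-representation** — hypergeometric-tail enrichment of the
   changed-gene set and of each module, BH-corrected.

Synthetic-data generators (`generate_cohort()`,
`generate_reference_panel()`, `generate_ppi()`,
`generate_go_annotation()`) emulate every input with planted ground truth,
so the whole chain is testable offline.

## Worked example

The numbered scripts under `analysis/` run the chain stage by stage on a
simulated 50-smoker / 61-non-smoker cohort (2,000 probes, 12 slides, 150
planted effect probes at Δβ 0.10–0.15) and a 5-cell-type reference panel,
writing every intermediate under `results/pipeline/`. Their printed
output:

```
$ Rscript analysis/01_simulate.R
cohort: 2000 probes x 111 samples (50 smokers), 150 planted effects
panel: 5 cell types x 6 replicates, 200 planted cell-type sites

$ Rscript analysis/02_cell_composition.R
207 of 2000 probes significantly differ between cell types (BH 0.05)
PCA on top 100 sites: first 5 components explain 21.7% of variance

$ Rscript analysis/03_probe_ewas.R
fitted 2000 probes; 158 significant at FDR 0.05 (0 skipped)
planted-effect recovery: 100% of 150 planted probes below FDR 0.05

$ Rscript analysis/04_promoter_network.R
300 genes with >= 1 promoter probe tested; min p' = 4.58e-41
weighted network: 300 genes, 1284 interactions (0 unmapped dropped)

$ Rscript analysis/05_module_search.R
2 significant sub-network(s) accepted
  module 1: 15 genes, score 0.864, empirical p 0.005, best Jaccard vs truth 1.00
  module 2: 7 genes, score 0.742, empirical p 0.015, best Jaccard vs truth 0.86

$ Rscript analysis/06_go_enrichment.R
genome-wide mode: 99 changed genes of 300 in the universe
module 1: planted term ranks 1 (corrected p 1.62e-04)
module 2: planted term ranks 1 (corrected p 1.01e-04)
```

Reading the numbers: 207 of 2,000 panel probes separate the five cell
types after FDR correction (200 were planted); the EWAS recovers all 150
planted smoking effects among 158 FDR-significant probes (the excess is
consistent with the FDR guarantee); the module search recovers both
planted sub-networks — the 15-gene module exactly, the 6-gene module with
one extra member — each well below the 0.05 empirical significance level;
and for each module, the GO term planted at odds ratio 20 ranks first in
its enrichment table.

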