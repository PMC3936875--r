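#!/usr/bin/env Rscript
# Stage 2 — cell-mixture surrogates: rank panel probes by the one-way
# cell-type F-test, BH-correct, take the top 100 sites, and compute the
# cohort's first 5 principal-component scores at those sites.

library(smokeMethNet)

out <- "results/pipeline"
panel_betas <- read_beta_matrix(file.path(out, "panel_betas.tsv"))
labels_tab <- read.delim(file.path(out, "panel_labels.tsv"))
labels <- setNames(labels_tab$cell_type, labels_tab$sample_id)
cohort <- read_beta_matrix(file.path(out, "cohort_betas.tsv"))

ranking <- derive_celltype_sites(panel_betas, labels, alpha = 0.05)
cat(sprintf("%d of %d probes significantly differ between cell types (BH 0.05)\n",
            attr(ranking, "n_significant"), attr(ranking, "n_tested")))
write.table(ranking, file.path(out, "celltype_sites.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

surr <- compute_surrogates(cohort, ranking, top_k = 100L, n_components = 5L)
cat(sprintf("PCA on top %d sites: first 5 components explain %.1f%% of variance\n",
            surr$n_sites_used, 100 * sum(surr$explained_variance)))
write.table(data.frame(sample_id = rownames(surr$scores), surr$scores),
            file.path(out, "surrogates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
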