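#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs: a 50-smoker / 61-non-smoker cohort
# on a 2,000-probe array with 12 slides and 2 plates, and a 5-cell-type
# purified reference panel. All downstream stages read the files written
# here; ground truth goes to results/ for later scoring.

library(smokeMethNet)

seed <- 20140222L
out <- "results/pipeline"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- reference_panel_spec(seed = derive_seed(seed, "panel"))
# demo cohort: enough promoter-level signal that the network stage has a
# meaningful low-p' gene pool (150 effect probes at delta 0.10-0.15)
spec <- cohort_spec(n_effect_probes = 150L,
                    effect_delta_range = c(0.10, 0.15), seed = seed)

ref <- generate_reference_panel(panel, n_probes = spec$n_probes)
cohort <- generate_cohort(spec, panel)

write_beta_matrix(cohort$betas, file.path(out, "cohort_betas.tsv"))
write_beta_matrix(ref$betas, file.path(out, "panel_betas.tsv"))
write.table(cohort$sheet, file.path(out, "sample_sheet.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = names(ref$labels),
                       cell_type = unname(ref$labels)),
            file.path(out, "panel_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_probe_annotation(cohort$annotation,
                       file.path(out, "probe_annotation.tsv"))
writeLines(cohort$truth$effect_probe_ids,
           file.path(out, "truth_effect_probes.txt"))

cat(sprintf("cohort: %d probes x %d samples (%d smokers), %d planted effects\n",
            nrow(cohort$betas$values), ncol(cohort$betas$values),
            sum(cohort$sheet$smoker), length(cohort$truth$effect_probe_ids)))
cat(sprintf("panel: %d cell types x %d replicates, %d planted cell-type sites\n",
            length(panel$cell_types), panel$n_replicates_per_type,
            length(ref$truth$celltype_probe_ids)))
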