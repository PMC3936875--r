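#!/usr/bin/env Rscript
# Stage 5 — greedy local-modularity module discovery with the permutation
# null, scored against the planted module memberships.

library(smokeMethNet)

seed <- 20140222L
out <- "results/pipeline"
edges <- read_edge_list(file.path(out, "ppi_edges.tsv"))
gene_p <- read.delim(file.path(out, "gene_pvalues.tsv"))
net <- build_weighted_network(edges, gene_p)

cfg <- search_config(n_null = 200L, max_seeds = 100L,
                     seed = derive_seed(seed, "search"))
mods <- find_modules(net, cfg)
cat(sprintf("%d significant sub-network(s) accepted\n", length(mods)))

truth <- strsplit(readLines(file.path(out, "truth_modules.txt")), ";")
jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
for (i in seq_along(mods)) {
  m <- mods[[i]]
  best <- if (length(truth)) max(vapply(truth, jac, numeric(1L),
                                        a = m$members)) else NA
  cat(sprintf("  module %d: %d genes, score %.3f, empirical p %.3f, best Jaccard vs truth %.2f\n",
              i, m$size, m$score, m$empirical_p, best))
}

mod_tab <- data.frame(
  module = seq_along(mods),
  size = vapply(mods, `[[`, integer(1L), "size"),
  score = vapply(mods, `[[`, numeric(1L), "score"),
  empirical_p = vapply(mods, `[[`, numeric(1L), "empirical_p"),
  members = vapply(mods, function(m) paste(m$members, collapse = ";"),
                   character(1L)))
write.table(mod_tab, file.path(out, "modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
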