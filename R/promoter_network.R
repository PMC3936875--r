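# Promoter-level differential methylation and the p-value-weighted PPI
# network. Gene-level signal: flatten all (promoter probe x sample) betas
# into one vector per smoking group, unpaired t-test, BH across genes.
# Edge weight between genes i and j:
#   w_ij = log(p'_i * p'_j) / log(p'_min^2)
# which maps pair significance into [0, 1] (1 when both genes sit at the
# table minimum, 0 when both are at p' = 1). The log base cancels.

#' Map genes to their promoter-category probes
#'
#' @param annotation Probe annotation (see [read_probe_annotation()]).
#' @param promoter_categories Gene-region categories counted as promoter
#'   (default TSS1500 + TSS200).
#' @return Named list: gene symbol -> character vector of probe ids. A
#'   probe annotated to k genes appears in all k sets; genes with no
#'   promoter probe are omitted.
#' @export
assign_promoter_probes <- function(annotation,
                                   promoter_categories = c("TSS1500",
                                                           "TSS200")) {
  bad <- setdiff(promoter_categories, PLACEMENT_LEVELS)
  if (length(bad)) stop(sprintf("unknown placement category '%s'", bad[1L]))
  keep <- annotation$placement %in% promoter_categories &
    lengths(annotation$gene_symbols) > 0L
  if (!any(keep)) return(list())
  probe <- rep(annotation$probe_id[keep],
               lengths(annotation$gene_symbols[keep]))
  gene <- toupper(unlist(annotation$gene_symbols[keep], use.names = FALSE))
  lapply(split(probe, gene), unique)
}

#' Promoter-level t-tests between smokers and non-smokers
#'
#' For each gene, builds two flattened promoter methylation vectors — all
#' unmasked (probe x sample) betas of its promoter probes, one vector per
#' smoking group — runs an unpaired t-test between them, and BH-adjusts
#' across all genes tested.
#'
#' @param betas Cohort [beta_matrix()].
#' @param sheet Sample sheet.
#' @param mapping Gene -> probe-id sets from [assign_promoter_probes()].
#' @param equal_variance Pooled-variance t-test (default) or Welch.
#' @param per_sample_mean Collapse each sample's promoter probes to their
#'   mean before testing (one value per sample) instead of flattening all
#'   probe-by-sample values into one vector (default `FALSE`, the literal
#'   two-vector construction; the collapsed mode changes the degrees of
#'   freedom materially).
#' @return data.frame (gene, raw_p, adjusted_p, n_probes,
#'   n_smoker_values, n_nonsmoker_values), one row per tested gene; genes
#'   whose vectors have < 2 values in either group are dropped and listed
#'   in the `dropped` attribute.
#' @export
promoter_t_tests <- function(betas, sheet, mapping, equal_variance = TRUE,
                             per_sample_mean = FALSE) {
  stopifnot(inherits(betas, "beta_matrix"))
  idx <- match(colnames(betas$values), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet missing cohort sample(s)")
  smoker_cols <- sheet$smoker[idx] == 1L
  genes <- names(mapping)
  raw_p <- rep(NA_real_, length(genes))
  np <- nv_s <- nv_n <- integer(length(genes))
  for (g in seq_along(genes)) {
    pr <- intersect(mapping[[g]], rownames(betas$values))
    if (length(pr) == 0L) next
    vs <- betas$values[pr, smoker_cols, drop = FALSE]
    vn <- betas$values[pr, !smoker_cols, drop = FALSE]
    if (per_sample_mean) {
      vs <- colMeans(vs, na.rm = TRUE)
      vn <- colMeans(vn, na.rm = TRUE)
    }
    vs <- vs[!is.na(vs) & is.finite(vs)]
    vn <- vn[!is.na(vn) & is.finite(vn)]
    if (length(vs) < 2L || length(vn) < 2L) next
    tt <- unpaired_t_test(vs, vn, equal_variance = equal_variance)
    raw_p[g] <- tt$p
    np[g] <- length(pr); nv_s[g] <- length(vs); nv_n[g] <- length(vn)
  }
  ok <- !is.na(raw_p)
  if (!any(ok)) stop("no gene could be tested")
  res <- data.frame(gene = genes[ok], raw_p = raw_p[ok],
                    adjusted_p = bh_adjust(raw_p[ok]),
                    n_probes = np[ok], n_smoker_values = nv_s[ok],
                    n_nonsmoker_values = nv_n[ok],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "dropped") <- genes[!ok]
  res
}

#' Edge weight from two adjusted gene p-values
#'
#' `w = log(p_i * p_j) / log(p_min^2)`, vectorized over `p_i`/`p_j`.
#' P-values below `floor` are clipped to it before taking logs.
#'
#' @param p_i,p_j Adjusted p-values of the two endpoint genes.
#' @param p_min Minimum adjusted p-value over the whole gene table (< 1).
#' @param floor Numerical floor for p-values (default 1e-300).
#' @return Weight(s) in \[0, 1\].
#' @export
edge_weight <- function(p_i, p_j, p_min, floor = 1e-300) {
  if (any(p_min >= 1)) {
    stop("unweightable network: minimum adjusted p is >= 1")
  }
  if (any(p_i < p_min) || any(p_j < p_min)) {
    stop("`p_min` must be the table minimum")
  }
  p_i <- pmax(p_i, floor); p_j <- pmax(p_j, floor)
  p_min <- pmax(p_min, floor)
  (log(p_i) + log(p_j)) / (2 * log(p_min)) + 0
}

#' Build the p-value-weighted protein-interaction network
#'
#' Keeps edges whose two endpoints both appear in the gene p' table,
#' assigns each the [edge_weight()] from the endpoint p's, and attaches
#' `-log10(p')` as the node attribute used downstream for tie-breaking and
#' visualization. The number of unmapped (dropped) edges is recorded in the
#' graph attribute `n_dropped_edges`.
#'
#' @param edges Canonical edge data.frame (see [read_edge_list()]).
#' @param table Gene p' table from [promoter_t_tests()].
#' @return An undirected `igraph` with edge attribute `weight` and node
#'   attributes `name`, `p_adjusted`, `neg_log10_p`.
#' @export
build_weighted_network <- function(edges, table) {
  p <- stats::setNames(table$adjusted_p, toupper(table$gene))
  keep <- edges$a %in% names(p) & edges$b %in% names(p)
  if (!any(keep)) stop("no interaction maps to the gene table")
  kept <- edges[keep, , drop = FALSE]
  p_min <- min(p)
  w <- edge_weight(p[kept$a], p[kept$b], p_min)
  g <- igraph::graph_from_data_frame(
    data.frame(kept, weight = unname(w)), directed = FALSE)
  igraph::V(g)$p_adjusted <- unname(p[igraph::V(g)$name])
  igraph::V(g)$neg_log10_p <- -log10(pmax(unname(p[igraph::V(g)$name]),
                                          1e-300))
  g <- igraph::set_graph_attr(g, "n_dropped_edges", sum(!keep))
  g <- igraph::set_graph_attr(g, "p_min", p_min)
  g
}
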