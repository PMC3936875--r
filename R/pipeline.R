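# End-to-end orchestration over synthetic or user-supplied inputs, plus the
# platform-concordance check (array vs an independent assay at one locus).

#' Run the full analysis pipeline on synthetic data
#'
#' Generates (or reuses) the synthetic inputs, then runs every stage in
#' order — reference-panel site selection, cohort surrogate PCA, per-probe
#' EWAS, promoter-level t-tests, weighted-network construction, greedy
#' module search, and GO enrichment of the changed genes and of each
#' accepted module — writing all intermediates as files under `out_dir` and
#' returning a manifest of per-stage record counts and file digests.
#' Identical `seed` and configuration give byte-identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed fanned out to per-stage streams.
#' @param spec Cohort settings ([cohort_spec()]); seed is overridden by
#'   `seed`.
#' @param panel Reference-panel settings ([reference_panel_spec()]).
#' @param search Module-search settings ([search_config()]).
#' @param alpha_ewas,alpha_modules Significance levels (default 0.05).
#' @param top_k,n_components Surrogate-PCA settings (defaults 100 and 5).
#' @param promoter_categories Promoter placement categories.
#' @param n_go_terms Number of synthetic GO terms.
#' @return The run manifest (invisibly written to `manifest.tsv` as well):
#'   list with `seed`, `counts`, `files`, `digests` and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         spec = cohort_spec(),
                         panel = reference_panel_spec(),
                         search = search_config(n_null = 200L,
                                                max_seeds = 60L),
                         alpha_ewas = 0.05, alpha_modules = 0.05,
                         top_k = 100L, n_components = 5L,
                         promoter_categories = c("TSS1500", "TSS200"),
                         n_go_terms = 50L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec$seed <- seed
  panel$seed <- derive_seed(seed, "panel")
  search$seed <- derive_seed(seed, "search")
  search$alpha <- alpha_modules

  ref <- generate_reference_panel(panel, n_probes = spec$n_probes)
  cohort <- generate_cohort(spec, panel)
  write_beta_matrix(cohort$betas, file.path(out_dir, "cohort_betas.tsv"))
  utils::write.table(cohort$sheet, file.path(out_dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_probe_annotation(cohort$annotation,
                         file.path(out_dir, "probe_annotation.tsv"))

  ranking <- derive_celltype_sites(ref$betas, ref$labels)
  utils::write.table(ranking, file.path(out_dir, "celltype_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  surr <- compute_surrogates(cohort$betas, ranking, top_k = top_k,
                             n_components = n_components)
  utils::write.table(
    data.frame(sample_id = rownames(surr$scores), surr$scores),
    file.path(out_dir, "surrogates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ewas <- fit_probe_models(cohort$betas, cohort$sheet, surr)
  write_ranked_table(ewas, file.path(out_dir, "ewas_ranked.tsv"),
                     annotation = cohort$annotation)
  counts_ewas <- summarize_counts(ewas, alpha_ewas)

  mapping <- assign_promoter_probes(cohort$annotation, promoter_categories)
  gene_p <- promoter_t_tests(cohort$betas, cohort$sheet, mapping)
  utils::write.table(gene_p, file.path(out_dir, "gene_pvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gp_vec <- stats::setNames(gene_p$adjusted_p, gene_p$gene)
  # plant demonstration modules among the lowest-p' genes; the pool cutoff
  # adapts so the two default modules always fit
  sizes <- c(6L, 15L)
  pool_n <- min(length(gp_vec),
                max(2L * sum(sizes), ceiling(0.15 * length(gp_vec))))
  ppi <- generate_ppi(gp_vec, n_modules = 2L, module_sizes = sizes,
                      low_p_max = sort(gp_vec)[pool_n],
                      seed = derive_seed(seed, "ppi_stage"))
  write_edge_list(ppi$edges, file.path(out_dir, "ppi_edges.tsv"))
  network <- build_weighted_network(ppi$edges, gene_p)
  write_network_export(network, file.path(out_dir, "network"))
  modules <- find_modules(network, search)
  if (length(modules)) {
    mod_tab <- data.frame(
      module = seq_along(modules),
      size = vapply(modules, `[[`, integer(1L), "size"),
      score = vapply(modules, `[[`, numeric(1L), "score"),
      empirical_p = vapply(modules, `[[`, numeric(1L), "empirical_p"),
      members = vapply(modules, function(m) paste(m$members, collapse = ";"),
                       character(1L)))
  } else {
    mod_tab <- data.frame(module = integer(0), size = integer(0),
                          score = numeric(0), empirical_p = numeric(0),
                          members = character(0))
  }
  utils::write.table(mod_tab, file.path(out_dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  universe <- unique(toupper(gene_p$gene))
  go <- generate_go_annotation(universe, n_terms = n_go_terms,
                               planted = lapply(modules, `[[`, "members"),
                               seed = derive_seed(seed, "go_stage"))
  write_gmt(go, file.path(out_dir, "go_annotation.gmt"))
  changed <- changed_genes_from_ewas(ewas, cohort$annotation, alpha_ewas)
  genomewide_go <- NULL
  if (length(intersect(changed$changed, changed$universe)) > 0L &&
      length(changed$changed) > 0L) {
    genomewide_go <- enrich(changed$changed, changed$universe, go)
    utils::write.table(genomewide_go,
                       file.path(out_dir, "go_genomewide.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  net_universe <- igraph::V(network)$name
  module_go <- lapply(seq_along(modules), function(i) {
    q <- intersect(modules[[i]]$members, net_universe)
    res <- enrich(q, net_universe, go)
    utils::write.table(res,
                       file.path(out_dir, sprintf("go_module%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    seed = seed,
    counts = list(
      n_probes = nrow(cohort$betas$values),
      n_samples = ncol(cohort$betas$values),
      n_celltype_sites_significant = attr(ranking, "n_significant"),
      n_surrogate_sites_used = surr$n_sites_used,
      n_surrogate_components = n_components,
      n_probes_fitted = nrow(ewas),
      n_probes_significant = counts_ewas$n_significant,
      n_promoter_genes = nrow(gene_p),
      n_edges_mapped = igraph::ecount(network),
      n_edges_dropped = igraph::graph_attr(network, "n_dropped_edges"),
      n_modules_accepted = length(modules),
      module_sizes = vapply(modules, `[[`, integer(1L), "size")),
    files = basename(files),
    digests = as.list(tools::md5sum(files)))
  man_tab <- data.frame(key = names(unlist(manifest$counts)),
                        value = unlist(manifest$counts))
  utils::write.table(man_tab, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$files <- c(manifest$files, "manifest.tsv")
  invisible(c(manifest,
              list(ewas = ewas, gene_p = gene_p, network = network,
                   modules = modules, ranking = ranking, surrogates = surr,
                   cohort = cohort, go = go,
                   genomewide_go = genomewide_go, module_go = module_go)))
}

#' Concordance between two methylation measurements of one locus
#'
#' Pearson correlation between paired per-sample methylation fractions from
#' two detection methods (e.g. array beta values vs quantitative-PCR
#' percent methylation), with an exported table of the paired values.
#'
#' @param x,y Named numeric vectors (names = sample ids) or two-column
#'   data.frames (sample_id, value).
#' @param path Optional TSV path for the paired values.
#' @return List with `r` and the paired data.frame.
#' @export
validate_concordance <- function(x, y, path = NULL) {
  as_named <- function(v) {
    if (is.data.frame(v)) stats::setNames(v[[2L]], as.character(v[[1L]]))
    else v
  }
  x <- as_named(x); y <- as_named(y)
  if (is.null(names(x)) || is.null(names(y))) {
    stop("both vectors must carry sample ids")
  }
  miss <- c(setdiff(names(x), names(y)), setdiff(names(y), names(x)))
  if (length(miss)) {
    stop(sprintf("misaligned sample ids: %s",
                 paste(unique(miss), collapse = ", ")))
  }
  y <- y[names(x)]
  r <- pearson_correlation(x, y)
  paired <- data.frame(sample_id = names(x), method_x = unname(x),
                       method_y = unname(y), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(paired, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(r = r, paired = paired)
}
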