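# Hypergeometric over-representation analysis, used in two modes: genome-
# wide changed-gene enrichment (all genes owning a significant probe) and
# per-sub-network enrichment (module members against the network universe).

#' Hypergeometric gene-set over-representation test
#'
#' For each term, tests whether the query over-represents the term's
#' members within the universe: upper-tail hypergeometric p on the overlap,
#' BH correction across the tested terms. Term members are intersected with
#' the universe first; terms with no universe member are skipped.
#'
#' @param query Character vector of query gene symbols (subset of
#'   `universe`, non-empty).
#' @param universe Character vector of universe gene symbols.
#' @param collection Gene-set collection (named list as from [read_gmt()]).
#' @param correction `"BH"` (default) or `"permutation"`: the latter
#'   estimates per-term FDR by resampling random query sets of equal size.
#' @param n_perm Resamples for the permutation mode (default 1000).
#' @param seed RNG seed for the permutation mode.
#' @return data.frame sorted ascending by raw p: term_id, term_name, total
#'   (term genes in universe), changed (term genes in query), raw_p,
#'   log10_p, corrected_p.
#' @export
enrich <- function(query, universe, collection, correction = c("BH",
                                                               "permutation"),
                   n_perm = 1000L, seed = 1L) {
  correction <- match.arg(correction)
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (length(query) == 0L) stop("empty query gene set")
  out <- setdiff(query, universe)
  if (length(out)) {
    stop(sprintf("query gene(s) outside the universe: %s",
                 paste(utils::head(out, 3L), collapse = ", ")))
  }
  members <- lapply(collection, function(g) intersect(toupper(g), universe))
  total <- lengths(members)
  keep <- total > 0L
  members <- members[keep]
  total <- total[keep]
  if (length(members) == 0L) stop("no term overlaps the universe")
  changed <- vapply(members, function(g) length(intersect(g, query)),
                    integer(1L))
  raw_p <- mapply(hypergeom_tail, changed, total,
                  MoreArgs = list(selected_size = length(query),
                                  universe_size = length(universe)))
  corrected <- if (correction == "BH") {
    bh_adjust(raw_p)
  } else {
    with_seed(derive_seed(seed, "enrich_perm"), {
      exceed <- numeric(length(raw_p))
      for (b in seq_len(n_perm)) {
        q <- sample(universe, length(query))
        ch <- vapply(members, function(g) length(intersect(g, q)),
                     integer(1L))
        pb <- mapply(hypergeom_tail, ch, total,
                     MoreArgs = list(selected_size = length(query),
                                     universe_size = length(universe)))
        exceed <- exceed + vapply(raw_p, function(x) mean(pb <= x),
                                  numeric(1L))
      }
      pmin(1, exceed / n_perm)
    })
  }
  nms <- attr(collection, "term_names")
  res <- data.frame(
    term_id = names(members),
    term_name = if (is.null(nms)) names(members)
                else unname(nms[names(members)]),
    total = total, changed = changed,
    raw_p = unname(raw_p), log10_p = log10(unname(raw_p)),
    corrected_p = unname(corrected),
    stringsAsFactors = FALSE)
  res <- res[order(res$raw_p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genes carrying significant probes, and the matching universe
#'
#' The changed set is every gene owning at least one probe with adjusted
#' p <= alpha; the universe is every gene owning at least one fitted probe.
#'
#' @param results Probe results from [fit_probe_models()].
#' @param annotation Probe annotation.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return List with `changed` and `universe` (character vectors).
#' @export
changed_genes_from_ewas <- function(results, annotation, alpha = 0.05) {
  idx <- match(results$probe_id, annotation$probe_id)
  genes_of <- annotation$gene_symbols[idx]
  fitted_genes <- unique(toupper(unlist(genes_of, use.names = FALSE)))
  sig <- results$adjusted_p <= alpha
  changed <- unique(toupper(unlist(genes_of[sig], use.names = FALSE)))
  list(changed = changed, universe = fitted_genes)
}
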