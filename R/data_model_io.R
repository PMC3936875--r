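#' Construct a beta-value matrix
#'
#' A `beta_matrix` holds methylation fractions (probes x samples) together
#' with a missingness mask. Masked cells (failed detection p, or missing on
#' input) carry `NA` in `values` and `TRUE` in `mask`. All unmasked values
#' must lie in \[0, 1\]; probe and sample ids must be unique.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   `rownames` (probe ids) and `colnames` (sample ids).
#' @param mask Optional logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry probe ids (rownames) and sample ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate probe id")
  if (anyDuplicated(colnames(values))) stop("duplicate sample id")
  if (is.null(mask)) mask <- is.na(values)
  stopifnot(is.logical(mask), all(dim(mask) == dim(values)))
  values[mask] <- NA_real_
  bad <- which(!mask & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s'",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  }
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (%d masked cells)\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Read a beta-value matrix, applying the detection-p filter
#'
#' Reads a rectangular TSV/CSV (first column probe ids, header row sample
#' ids). If a same-shape detection-p table is supplied, cells with detection
#' p strictly greater than `detection_p_max` are masked — values at exactly
#' the threshold are kept.
#'
#' @param path Path to the beta table.
#' @param detection_p_path Optional path to a same-shape detection-p table.
#' @param detection_p_max Detection-p threshold (default 0.05).
#' @param sep Field separator; tab by default, use "," for CSV.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, detection_p_path = NULL,
                             detection_p_max = 0.05, sep = "\t") {
  tab <- read_rectangular(path, sep)
  if (anyDuplicated(tab[[1L]])) {
    stop(sprintf("%s: duplicate probe id '%s'", path,
                 tab[[1L]][anyDuplicated(tab[[1L]])]))
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop(sprintf("%s: non-numeric beta values", path))
  rownames(values) <- tab[[1L]]
  mask <- is.na(values)
  if (!is.null(detection_p_path)) {
    dp <- read_rectangular(detection_p_path, sep)
    dpm <- as.matrix(dp[, -1L, drop = FALSE])
    rownames(dpm) <- dp[[1L]]
    if (!identical(dim(dpm), dim(values)) ||
        !identical(rownames(dpm), rownames(values)) ||
        !identical(colnames(dpm), colnames(values))) {
      stop("detection-p table does not match the beta table's shape/ids")
    }
    mask <- mask | (!is.na(dpm) & dpm > detection_p_max)
  }
  values[mask] <- NA_real_
  beta_matrix(values, mask)
}

read_rectangular <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "")
  if (ncol(tab) < 2L) stop(sprintf("%s: expected >= 2 columns", path))
  tab
}

#' Write a beta-value matrix (masked cells as NA)
#'
#' @param x A [beta_matrix()].
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_beta_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "beta_matrix"))
  out <- data.frame(probe_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet (sample_id, smoker, slide, plate)
#'
#' @param path TSV with columns sample_id, smoker (0/1), slide, plate.
#' @param sep Field separator.
#' @return A data.frame with smoker as integer and slide/plate as character.
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  sheet <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  need <- c("sample_id", "smoker", "slide", "plate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path,
                                 paste(miss, collapse = ", ")))
  if (!all(sheet$smoker %in% c(0L, 1L))) stop("smoker must be 0/1")
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id")
  sheet$smoker <- as.integer(sheet$smoker)
  sheet$slide <- as.character(sheet$slide)
  sheet$plate <- as.character(sheet$plate)
  sheet
}

# Closed vocabularies of the 450K manifest columns we consume.
PLACEMENT_LEVELS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body",
                      "3'UTR", "intergenic")
ISLAND_LEVELS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                   "open_sea")

#' Read a probe annotation manifest
#'
#' Columns: probe_id, gene_symbols (semicolon-delimited, possibly empty),
#' placement, island_status. Placement and island status must come from the
#' manifest's closed vocabularies.
#'
#' @param path TSV path.
#' @param sep Field separator.
#' @return data.frame with a `gene_symbols` list-column of character vectors.
#' @export
read_probe_annotation <- function(path, sep = "\t") {
  ann <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = NULL,
                           quote = "", comment.char = "")
  need <- c("probe_id", "gene_symbols", "placement", "island_status")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop(sprintf("%s: missing column(s) %s", path,
                                 paste(miss, collapse = ", ")))
  bad <- setdiff(unique(ann$placement), PLACEMENT_LEVELS)
  if (length(bad)) stop(sprintf("%s: unknown placement '%s'", path, bad[1L]))
  bad <- setdiff(unique(ann$island_status), ISLAND_LEVELS)
  if (length(bad)) stop(sprintf("%s: unknown island status '%s'",
                                path, bad[1L]))
  ann$gene_symbols <- lapply(strsplit(as.character(ann$gene_symbols), ";",
                                      fixed = TRUE),
                             function(g) toupper(g[nzchar(g)]))
  ann
}

#' @rdname read_probe_annotation
#' @param ann Annotation data.frame as returned by `read_probe_annotation`.
#' @export
write_probe_annotation <- function(ann, path, sep = "\t") {
  out <- ann
  out$gene_symbols <- vapply(ann$gene_symbols, paste, character(1L),
                             collapse = ";")
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected protein-interaction edge list
#'
#' Accepts a plain two-column table or a MITAB-style multi-column file via
#' `columns`. Symbols are uppercased, self-loops dropped, and duplicate
#' edges (in either orientation) collapsed; the number of dropped records is
#' attached as attribute `n_dropped`.
#'
#' @param path Path to the edge file.
#' @param columns Length-2 integer vector: which columns hold the two
#'   interactor symbols (default `c(1, 2)`).
#' @param sep Field separator.
#' @param header Does the file carry a header row?
#' @return data.frame with columns `a`, `b` (a < b lexically), one row per
#'   unique undirected edge.
#' @export
read_edge_list <- function(path, columns = c(1L, 2L), sep = "\t",
                           header = FALSE) {
  if (length(readLines(path, n = 1L)) == 0L) {
    stop(sprintf("%s: empty edge list", path))
  }
  raw <- utils::read.table(path, header = header, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  if (nrow(raw) == 0L) stop(sprintf("%s: empty edge list", path))
  if (max(columns) > ncol(raw)) {
    stop(sprintf("%s: requested columns %s but file has %d columns",
                 path, paste(columns, collapse = ","), ncol(raw)))
  }
  a <- toupper(as.character(raw[[columns[1L]]]))
  b <- toupper(as.character(raw[[columns[2L]]]))
  canonicalize_edges(a, b)
}

canonicalize_edges <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- lo != hi
  edges <- unique(data.frame(a = lo[keep], b = hi[keep],
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  attr(edges, "n_dropped") <- length(a) - nrow(edges)
  edges
}

#' @rdname read_edge_list
#' @param edges Canonical edge data.frame.
#' @export
write_edge_list <- function(edges, path, sep = "\t") {
  utils::write.table(edges[, c("a", "b")], path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: term_id, term_name, then member symbols, tab-split.
#' @return Named list of character vectors (names = term ids), with a
#'   `term_names` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("%s: empty GMT", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) stop(sprintf("%s: line %d has fewer than 3 fields",
                                  path, short[1L]))
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop(sprintf("%s: duplicate term id", path))
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- ids
  attr(sets, "term_names") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), ids)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene sets with a `term_names` attribute.
#' @export
write_gmt <- function(sets, path) {
  nm <- attr(sets, "term_names")
  if (is.null(nm)) nm <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(nm[id]), sets[[id]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked EWAS probe table
#'
#' Emits the Table-2-style layout: probe_id, gene, placement, island_status,
#' group mean betas (2 decimals), raw and adjusted p (3 significant digits,
#' scientific), sorted ascending by raw p.
#'
#' @param results data.frame of probe results (see [fit_probe_models()]).
#' @param path Output TSV path.
#' @param annotation Optional probe annotation to supply gene/placement/
#'   island columns; unannotated probes print empty strings.
#' @export
write_ranked_table <- function(results, path, annotation = NULL) {
  results <- results[order(results$raw_p), , drop = FALSE]
  gene <- placement <- island <- rep("", nrow(results))
  if (!is.null(annotation) && nrow(results) > 0L) {
    idx <- match(results$probe_id, annotation$probe_id)
    hit <- !is.na(idx)
    gene[hit] <- vapply(annotation$gene_symbols[idx[hit]], paste,
                        character(1L), collapse = ";")
    placement[hit] <- annotation$placement[idx[hit]]
    island[hit] <- annotation$island_status[idx[hit]]
  }
  out <- data.frame(
    probe_id = results$probe_id,
    gene = gene, placement = placement, island_status = island,
    mean_beta_smokers = sprintf("%.2f", results$mean_beta_smokers),
    mean_beta_nonsmokers = sprintf("%.2f", results$mean_beta_nonsmokers),
    raw_p = sprintf("%.2E", results$raw_p),
    adjusted_p = sprintf("%.2E", results$adjusted_p),
    stringsAsFactors = FALSE)
  if (nrow(results) == 0L) out <- out[0L, , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a weighted network as SIF plus attribute tables
#'
#' Writes `<stem>.sif` (edge list, interaction type "pp"), `<stem>_edges.tsv`
#' (edge weights, the line-width attribute) and `<stem>_nodes.tsv`
#' (-log10 adjusted gene p, the node-colour attribute), loadable by standard
#' graph-visualization tools.
#'
#' @param network An `igraph` weighted network (see
#'   [build_weighted_network()]).
#' @param stem Output path stem.
#' @export
write_network_export <- function(network, stem) {
  el <- igraph::as_edgelist(network)
  sif <- data.frame(a = el[, 1L], type = "pp", b = el[, 2L])
  utils::write.table(sif, paste0(stem, ".sif"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ew <- data.frame(a = el[, 1L], b = el[, 2L],
                   weight = igraph::E(network)$weight)
  utils::write.table(ew, paste0(stem, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nodes <- data.frame(gene = igraph::V(network)$name,
                      neg_log10_p = igraph::V(network)$neg_log10_p)
  utils::write.table(nodes, paste0(stem, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stem)
}
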