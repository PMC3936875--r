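# Cell-mixture surrogate derivation: rank reference-panel probes by a
# one-way cell-type F-test, take the top sites, and use the cohort's PCA
# scores at those sites as covariates for the EWAS.

#' Rank probes by differential methylation across purified cell types
#'
#' Per probe, a one-way fixed-effects linear model of beta on cell-type
#' indicators (equivalently a one-way ANOVA F-test), complete-case per
#' probe, with BH adjustment across all tested probes.
#'
#' @param panel A [beta_matrix()] of purified-cell betas.
#' @param labels Cell type per panel sample (named by sample id or aligned
#'   to the panel's column order).
#' @param alpha BH significance threshold for site selection (default 0.05).
#' @return data.frame (probe_id, raw_p, adjusted_p, rank) of significant
#'   sites sorted ascending by raw p, with attributes `n_tested` and
#'   `n_significant`.
#' @export
derive_celltype_sites <- function(panel, labels, alpha = 0.05) {
  stopifnot(inherits(panel, "beta_matrix"))
  if (!is.null(names(labels))) labels <- labels[colnames(panel$values)]
  labels <- as.character(labels)
  if (length(labels) != ncol(panel$values) || anyNA(labels)) {
    stop("`labels` must give a cell type for every panel sample")
  }
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 cell types")
  if (any(tab < 2L)) stop("every cell type needs at least 2 replicates")

  M <- panel$values
  obs <- !is.na(M)
  M0 <- ifelse(obs, M, 0)
  G <- stats::model.matrix(~ labels - 1)            # samples x k indicators
  k <- ncol(G)
  gsum <- M0 %*% G
  gcnt <- obs %*% G
  n_i <- rowSums(obs)
  grand <- rowSums(M0) / n_i
  gmean <- gsum / ifelse(gcnt > 0, gcnt, NA)
  ssb <- rowSums(gcnt * (gmean - grand)^2, na.rm = TRUE)
  sst <- rowSums(M0^2) - n_i * grand^2
  ssw <- pmax(sst - ssb, 0)
  df2 <- n_i - k
  testable <- df2 > 0 & apply(gcnt >= 1, 1L, all)
  Fstat <- (ssb / (k - 1)) / (ssw / df2)
  raw_p <- rep(NA_real_, nrow(M))
  raw_p[testable] <- ifelse(ssw[testable] == 0 & ssb[testable] == 0, 1,
                            stats::pf(Fstat[testable], k - 1, df2[testable],
                                      lower.tail = FALSE))
  tested <- which(!is.na(raw_p))
  adj <- bh_adjust(raw_p[tested])
  res <- data.frame(probe_id = rownames(M)[tested],
                    raw_p = raw_p[tested], adjusted_p = adj,
                    stringsAsFactors = FALSE)
  res <- res[order(res$raw_p, res$probe_id), , drop = FALSE]
  sig <- res[res$adjusted_p <= alpha, , drop = FALSE]
  if (nrow(sig)) sig$rank <- seq_len(nrow(sig))
  else sig$rank <- integer(0)
  rownames(sig) <- NULL
  attr(sig, "n_tested") <- length(tested)
  attr(sig, "n_significant") <- nrow(sig)
  sig
}

#' Compute cell-mixture surrogate covariates by PCA
#'
#' Takes the cohort betas at the top `top_k` reference-derived sites (ties
#' at the boundary raw p are all included) and returns the first
#' `n_components` principal-component sample scores of the column-centred,
#' unscaled samples-by-sites matrix. Masked cells are imputed with the
#' probe's mean before the PCA. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param cohort Cohort [beta_matrix()].
#' @param ranking Site ranking from [derive_celltype_sites()].
#' @param top_k Number of top sites (default 100).
#' @param n_components Number of components to return (default 5).
#' @return List with `scores` (samples x components, zero mean per column)
#'   and `explained_variance` (fraction per returned component).
#' @export
compute_surrogates <- function(cohort, ranking, top_k = 100L,
                               n_components = 5L) {
  stopifnot(inherits(cohort, "beta_matrix"))
  if (nrow(ranking) == 0L) stop("empty site ranking")
  if (ncol(cohort$values) < n_components + 1L) {
    stop("need more cohort samples than components")
  }
  k_eff <- min(top_k, nrow(ranking))
  cut_p <- ranking$raw_p[k_eff]
  sites <- ranking$probe_id[ranking$raw_p <= cut_p]   # ties included
  present <- intersect(sites, rownames(cohort$values))
  if (length(present) < length(sites)) {
    warning(sprintf("%d of %d selected sites absent from the cohort; using %d",
                    length(sites) - length(present), length(sites),
                    length(present)))
  }
  if (length(present) < n_components) {
    stop("fewer selected sites than requested components")
  }
  X <- t(cohort$values[present, , drop = FALSE])      # samples x sites
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  if (all(apply(X, 2L, stats::var) == 0)) {
    stop("degenerate input: no variance across samples at the selected sites")
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_components <- as.integer(n_components)
  scores <- pr$x[, seq_len(n_components), drop = FALSE]
  for (c in seq_len(n_components)) {
    j <- which.max(abs(pr$rotation[, c]))
    if (pr$rotation[j, c] < 0) scores[, c] <- -scores[, c]
  }
  colnames(scores) <- paste0("PC", seq_len(n_components))
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores,
       explained_variance = ev[seq_len(n_components)],
       n_sites_used = length(present))
}
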