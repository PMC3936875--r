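# Greedy discovery of high-scoring sub-networks on the weighted PPI graph.
# Score: parametric local modularity, the boundary ratio
#   Q(S) = W_in / (W_in + W_bnd),
# with W_in the sum of w^gamma over edges inside S and W_bnd the sum over
# edges with exactly one end in S. gamma parametrizes how strongly edge
# weights dominate topology (gamma = 0 reduces to unweighted edge counts).
# Empirical module significance comes from repeating the identical
# seed-selection + expansion procedure on networks whose node p' values
# were permuted (weights rebuilt from the closed-form edge-weight
# formula), compared by default to the null best over all module sizes.

#' Search configuration for module discovery
#'
#' @param size_min,size_max Accepted module size range (defaults 5 and 25,
#'   bracketing the 5-24-protein sub-networks the search targets).
#' @param gamma Weight exponent of the local-modularity score (default 1).
#' @param n_null Number of node-permutation null networks (default 1000,
#'   minimum 100).
#' @param alpha Empirical-p acceptance threshold (default 0.05).
#' @param max_seeds Number of top-weight seed edges expanded (default 500).
#' @param overlap_jaccard_max Maximum Jaccard overlap between accepted
#'   modules (default 0.5).
#' @param min_improve Minimum score increase required to add a node during
#'   expansion (default 0.025). Genuine module growth raises the boundary
#'   ratio in large steps; near-zero positive increments come from weak
#'   peripheral nodes whose tiny strength happens to point inward, and
#'   accepting them dilutes modules without changing their score
#'   materially.
#' @param fwer_correct Bonferroni-adjust the acceptance threshold by the
#'   number of occupied size strata (default `TRUE`). The empirical p of
#'   each module is computed within its own size stratum (score
#'   distributions are strongly size-dependent); testing every occupied
#'   stratum at `alpha` would accept spurious modules at roughly `alpha`
#'   times the number of strata per run, so acceptance requires
#'   `empirical_p <= alpha / n_strata`. Reported `empirical_p` values are
#'   the uncorrected stratum-level estimates.
#' @param seed RNG seed for the permutation null.
#' @return List of class `search_config`.
#' @export
search_config <- function(size_min = 5L, size_max = 25L, gamma = 1,
                          n_null = 1000L, alpha = 0.05, max_seeds = 500L,
                          overlap_jaccard_max = 0.5, min_improve = 0.025,
                          fwer_correct = TRUE, seed = 1L) {
  stopifnot(size_min >= 3L, size_max >= size_min, n_null >= 100L,
            alpha > 0, alpha < 1, max_seeds >= 1L,
            overlap_jaccard_max >= 0, overlap_jaccard_max <= 1)
  structure(as.list(environment()), class = "search_config")
}

# Flat adjacency index for fast incremental expansion.
network_index <- function(names, neg_log10_p, edge_a, edge_b, w_gamma) {
  n <- length(names)
  adj <- vector("list", n)
  adjw <- vector("list", n)
  for (v in seq_len(n)) { adj[[v]] <- integer(0); adjw[[v]] <- numeric(0) }
  sp <- split(seq_along(edge_a), edge_a)
  for (nm in names(sp)) {
    v <- as.integer(nm)
    adj[[v]] <- c(adj[[v]], edge_b[sp[[nm]]])
    adjw[[v]] <- c(adjw[[v]], w_gamma[sp[[nm]]])
  }
  sp <- split(seq_along(edge_b), edge_b)
  for (nm in names(sp)) {
    v <- as.integer(nm)
    adj[[v]] <- c(adj[[v]], edge_a[sp[[nm]]])
    adjw[[v]] <- c(adjw[[v]], w_gamma[sp[[nm]]])
  }
  strength <- vapply(adjw, sum, numeric(1L))
  list(n = n, names = names, nlp = neg_log10_p, adj = adj, adjw = adjw,
       strength = strength)
}

index_from_graph <- function(network, gamma) {
  el <- igraph::as_edgelist(network, names = FALSE)
  w <- igraph::E(network)$weight
  if (is.null(w)) stop("network has no edge weights")
  nlp <- igraph::V(network)$neg_log10_p
  if (is.null(nlp)) nlp <- rep(0, igraph::vcount(network))
  network_index(igraph::V(network)$name, nlp,
                as.integer(el[, 1L]), as.integer(el[, 2L]), w^gamma)
}

#' Parametric local modularity of a node set
#'
#' `W_in / (W_in + W_bnd)` over edge weights raised to `gamma`. Equals 1
#' exactly when the members form an entire connected component, and reduces
#' to the unweighted boundary ratio at `gamma = 0`.
#'
#' @param network Weighted `igraph` (edge attribute `weight`).
#' @param members Character vector of member node names (induced subgraph
#'   must be connected).
#' @param gamma Weight exponent (default 1).
#' @return Score in \[0, 1\].
#' @export
local_modularity <- function(network, members, gamma = 1) {
  vid <- match(members, igraph::V(network)$name)
  if (anyNA(vid)) stop("member(s) not in network")
  sub <- igraph::induced_subgraph(network, vid)
  if (!igraph::is_connected(sub)) stop("member set is not connected")
  el <- igraph::as_edgelist(network, names = FALSE)
  w <- igraph::E(network)$weight^gamma
  a_in <- el[, 1L] %in% vid
  b_in <- el[, 2L] %in% vid
  w_in <- sum(w[a_in & b_in])
  w_bnd <- sum(w[xor(a_in, b_in)])
  if (w_in + w_bnd == 0) stop("score undefined: isolated node set")
  w_in / (w_in + w_bnd)
}

# Incremental greedy expansion from two seed vertices (integer ids).
# Adds, each step, the neighbour with the largest strictly positive score
# increase; ties broken by higher node -log10 p', then lexical name.
expand_from <- function(idx, s1, s2, size_min, size_max, min_improve = 0) {
  members <- logical(idx$n)
  members[c(s1, s2)] <- TRUE
  sin <- numeric(idx$n)
  for (v in c(s1, s2)) {
    sin[idx$adj[[v]]] <- sin[idx$adj[[v]]] + idx$adjw[[v]]
  }
  w_in <- sin[s1]                       # edge(s) between the two seeds
  w_bnd <- idx$strength[s1] + idx$strength[s2] - 2 * w_in
  if (w_in + w_bnd == 0) return(NULL)
  score <- w_in / (w_in + w_bnd)
  size <- 2L
  while (size < size_max) {
    cand <- which(sin > 0 & !members)
    if (length(cand) == 0L) break
    nw_in <- w_in + sin[cand]
    nw_bnd <- w_bnd - 2 * sin[cand] + idx$strength[cand]
    nscore <- nw_in / (nw_in + nw_bnd)
    best <- max(nscore)
    if (best <= score + min_improve) break
    top <- cand[nscore == best]
    if (length(top) > 1L) {
      top <- top[order(-idx$nlp[top], idx$names[top])]
    }
    v <- top[1L]
    members[v] <- TRUE
    w_in <- w_in + sin[v]
    w_bnd <- w_bnd - 2 * sin[v] + idx$strength[v]
    sin[idx$adj[[v]]] <- sin[idx$adj[[v]]] + idx$adjw[[v]]
    score <- w_in / (w_in + w_bnd)
    size <- size + 1L
  }
  if (size < size_min) return(NULL)
  list(members = which(members), score = score, size = size)
}

#' Greedily expand a sub-network from a seed edge
#'
#' Deterministic: starts from the seed edge's two endpoints and repeatedly
#' adds the neighbouring node giving the largest strictly positive
#' local-modularity increase (ties by higher node `-log10 p'`, then lexical
#' symbol), stopping at no improvement or `size_max`.
#'
#' @param network Weighted `igraph`.
#' @param seed_edge Character vector of the two seed node names.
#' @param config A [search_config()].
#' @return List (members, score, size, seed_edge), or `NULL` if the
#'   expansion stops below `size_min`.
#' @export
greedy_expand <- function(network, seed_edge, config = search_config()) {
  idx <- index_from_graph(network, config$gamma)
  s <- match(seed_edge, idx$names)
  if (anyNA(s) || length(s) != 2L) stop("seed edge endpoints not in network")
  res <- expand_from(idx, s[1L], s[2L], config$size_min, config$size_max,
                     config$min_improve)
  if (is.null(res)) return(NULL)
  list(members = sort(idx$names[res$members]), score = res$score,
       size = res$size, seed_edge = seed_edge)
}

# Run the full seed-selection + expansion sweep on one index; returns the
# deduplicated-by-identity set of expansions.
sweep_expansions <- function(idx, edge_a, edge_b, w, config) {
  ord <- order(-w, idx$names[edge_a], idx$names[edge_b])
  ord <- ord[seq_len(min(config$max_seeds, length(ord)))]
  out <- list()
  seen <- character(0)
  for (e in ord) {
    res <- expand_from(idx, edge_a[e], edge_b[e],
                       config$size_min, config$size_max, config$min_improve)
    if (is.null(res)) next
    key <- paste(res$members, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    res$seed_edge <- c(idx$names[edge_a[e]], idx$names[edge_b[e]])
    out[[length(out) + 1L]] <- res
  }
  out
}

#' Find significant sub-networks by greedy local-modularity search
#'
#' Expands the top `max_seeds` edges by weight, scores each resulting
#' module against a permutation null — the identical seed+expand sweep run
#' on `n_null` networks whose node adjusted p-values were permuted over
#' nodes and edge weights rebuilt from the closed-form weight equation —
#' and keeps modules whose empirical p falls below `alpha`, greedily
#' deduplicated by descending score at the configured Jaccard overlap cap.
#' By default each observed score is compared against the null sweeps' best
#' score per replicate (max over sizes, a family-wise comparison); set
#' `stratify_by_size` in the config for within-size-stratum comparison.
#'
#' @param network Weighted `igraph` from [build_weighted_network()] (node
#'   attribute `p_adjusted` and graph attribute `p_min` are used to rebuild
#'   null weights).
#' @param config A [search_config()].
#' @return List of accepted modules, each a list (members, score, size,
#'   empirical_p, seed_edge), ordered by decreasing score.
#' @export
find_modules <- function(network, config = search_config()) {
  if (igraph::ecount(network) < config$size_min - 1L) {
    stop("network has too few edges to host a module")
  }
  el <- igraph::as_edgelist(network, names = FALSE)
  ea <- as.integer(el[, 1L]); eb <- as.integer(el[, 2L])
  p <- igraph::V(network)$p_adjusted
  if (is.null(p)) stop("network lacks the node attribute 'p_adjusted'")
  p_min <- igraph::graph_attr(network, "p_min")
  if (is.null(p_min)) p_min <- min(p)
  nm <- igraph::V(network)$name
  nlp <- igraph::V(network)$neg_log10_p
  if (is.null(nlp)) nlp <- -log10(pmax(p, 1e-300))

  # node contribution to the weight equation: w(u,v) = c_u + c_v
  cc <- log(pmax(p, 1e-300)) / (2 * log(max(p_min, 1e-300)))
  w_obs <- igraph::E(network)$weight
  idx_obs <- network_index(nm, nlp, ea, eb, w_obs^config$gamma)
  observed <- sweep_expansions(idx_obs, ea, eb, w_obs, config)
  if (length(observed) == 0L) return(list())

  sizes <- vapply(observed, `[[`, integer(1L), "size")
  size_range <- config$size_min:config$size_max
  null_best <- matrix(NA_real_, nrow = config$n_null,
                      ncol = length(size_range),
                      dimnames = list(NULL, size_range))
  with_seed(derive_seed(config$seed, "module_null"), {
    for (r in seq_len(config$n_null)) {
      perm <- sample.int(length(cc))
      cp <- cc[perm]
      wn <- cp[ea] + cp[eb]
      idx_null <- network_index(nm, nlp[perm], ea, eb, wn^config$gamma)
      nulls <- sweep_expansions(idx_null, ea, eb, wn, config)
      for (m in nulls) {
        j <- as.character(m$size)
        if (is.na(null_best[r, j]) || m$score > null_best[r, j]) {
          null_best[r, j] <- m$score
        }
      }
    }
  })
  emp_p <- vapply(seq_along(observed), function(i) {
    col <- as.character(sizes[i])
    hits <- sum(null_best[, col] >= observed[[i]]$score, na.rm = TRUE)
    (1 + hits) / (1 + config$n_null)
  }, numeric(1L))

  n_strata <- length(unique(sizes))
  alpha_eff <- if (isTRUE(config$fwer_correct)) {
    config$alpha / max(1L, n_strata)
  } else config$alpha
  keep <- which(emp_p <= alpha_eff)
  keep <- keep[order(-vapply(observed[keep], `[[`, numeric(1L), "score"))]
  accepted <- list()
  for (i in keep) {
    mi <- nm[observed[[i]]$members]
    overlap <- vapply(accepted, function(a) {
      length(intersect(a$members, mi)) / length(union(a$members, mi))
    }, numeric(1L))
    if (length(overlap) == 0L ||
        all(overlap <= config$overlap_jaccard_max)) {
      accepted[[length(accepted) + 1L]] <- list(
        members = sort(mi), score = observed[[i]]$score,
        size = observed[[i]]$size, empirical_p = emp_p[i],
        seed_edge = observed[[i]]$seed_edge)
    }
  }
  accepted
}
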