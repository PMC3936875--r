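# Independent reference implementations used to cross-check the package's
# statistics, kept deliberately naive (literal definitions, brute force).

# BH step-up by the literal definition: adjusted_i is the minimum over all
# j with p_j >= p_i of p_j * m / rank(p_j), capped at 1. O(n^2).
bh_oracle <- function(p, m = length(p)) {
  r <- rank(p, ties.method = "first")
  vapply(seq_along(p), function(i) {
    geq <- which(p >= p[i])
    min(1, min(p[geq] * m / r[geq]))
  }, numeric(1L))
}

# Hypergeometric upper tail by exhaustive summation of the pmf.
hyper_oracle <- function(q, k, n, N) {
  ks <- q:min(k, n)
  sum(choose(k, ks) * choose(N - k, n - ks)) / choose(N, n)
}

# Unweighted local modularity: counts of internal vs boundary edges.
count_modularity_oracle <- function(edges, members) {
  a_in <- edges$a %in% members
  b_in <- edges$b %in% members
  e_in <- sum(a_in & b_in)
  e_bnd <- sum(xor(a_in, b_in))
  e_in / (e_in + e_bnd)
}

# Best local modularity over every connected superset of the seed pair
# (exhaustive; graphs <= 10 nodes only).
brute_force_best <- function(network, seed_edge, gamma = 1,
                             size_max = 10L) {
  nodes <- igraph::V(network)$name
  others <- setdiff(nodes, seed_edge)
  best <- -Inf
  for (k in 0:min(length(others), size_max - 2L)) {
    combos <- if (k == 0L) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (extra in combos) {
      members <- c(seed_edge, extra)
      sub <- igraph::induced_subgraph(network,
                                      match(members,
                                            igraph::V(network)$name))
      if (!igraph::is_connected(sub)) next
      sc <- tryCatch(local_modularity(network, members, gamma),
                     error = function(e) NA_real_)
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  best
}

# Small deterministic beta fixture: n_probes x n_samples with optional
# group shift on selected probes.
tiny_betas <- function(n_probes = 20L, n_samples = 10L, seed = 42L) {
  set.seed(seed)
  vals <- matrix(runif(n_probes * n_samples, 0.2, 0.8),
                 nrow = n_probes,
                 dimnames = list(sprintf("cg%08d", seq_len(n_probes)),
                                 sprintf("S%03d", seq_len(n_samples))))
  beta_matrix(vals)
}

expect_setequal_chr <- function(x, y) {
  testthat::expect_setequal(as.character(x), as.character(y))
}

top30_path <- function() {
  system.file("extdata", "top30_smoking_probes.tsv",
              package = "smokeMethNet", mustWork = TRUE)
}

ARRAY_M_TOTAL <- 485577L
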