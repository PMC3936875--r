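# Small weighted graphs for exact checks.
toy_network <- function(edges, weights, p = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(edges, weight = weights), directed = FALSE)
  if (is.null(p)) p <- rep(0.5, igraph::vcount(g))
  igraph::V(g)$p_adjusted <- p
  igraph::V(g)$neg_log10_p <- -log10(p)
  g
}

test_that("local_modularity reproduces hand-computed scores", {
  # triangle of weight-1 edges with one weight-1 edge leaving
  g <- toy_network(data.frame(a = c("A", "B", "C", "A"),
                              b = c("B", "C", "A", "D")),
                   c(1, 1, 1, 1))
  expect_equal(local_modularity(g, c("A", "B", "C")), 3 / 4)
  # an entire connected component scores 1
  expect_equal(local_modularity(g, c("A", "B", "C", "D")), 1)
  expect_error(local_modularity(g, c("B", "D")), "connected")
  expect_error(local_modularity(g, c("A", "ZZ")), "not in network")
})

test_that("local_modularity at gamma 0 equals the unweighted counting
          oracle on random graphs", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    g <- igraph::sample_gnp(n, 0.4)
    while (igraph::ecount(g) < 4) g <- igraph::sample_gnp(n, 0.5)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
    igraph::V(g)$p_adjusted <- runif(n)
    igraph::V(g)$neg_log10_p <- -log10(igraph::V(g)$p_adjusted)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(a = el[, 1], b = el[, 2])
    comp <- igraph::components(g)
    big <- names(comp$membership[comp$membership == 1])
    if (length(big) < 3) next
    mem <- big[1:3]
    sub <- igraph::induced_subgraph(g, match(mem, igraph::V(g)$name))
    if (!igraph::is_connected(sub)) next
    expect_equal(local_modularity(g, mem, gamma = 0),
                 count_modularity_oracle(edges, mem), tolerance = 1e-12)
  }
})

test_that("local_modularity is monotone under internal-edge addition and
          boundary-edge removal", {
  g <- toy_network(data.frame(a = c("A", "B", "C", "A", "B"),
                              b = c("B", "C", "D", "D", "E")),
                   c(0.9, 0.8, 0.3, 0.7, 0.4))
  mem <- c("A", "B", "C")
  base <- local_modularity(g, mem)
  # add internal edge A-C
  g2 <- igraph::add_edges(g, match(c("A", "C"), igraph::V(g)$name),
                          attr = list(weight = 0.5))
  expect_gte(local_modularity(g2, mem), base)
  # remove boundary edge B-E
  g3 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c("B", "E")))
  expect_gte(local_modularity(g3, mem), base)
})

test_that("greedy_expand is deterministic and bounded by brute force on
          small graphs", {
  set.seed(62)
  cfg <- search_config(size_min = 3L, size_max = 10L, n_null = 100L,
                       min_improve = 0)
  for (i in 1:10) {
    n <- sample(6:9, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) < 5) next
    igraph::V(g)$name <- LETTERS[seq_len(n)]
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.05, 1)
    p <- runif(n)
    igraph::V(g)$p_adjusted <- p
    igraph::V(g)$neg_log10_p <- -log10(p)
    el <- igraph::as_edgelist(g)
    seed_edge <- c(el[1, 1], el[1, 2])
    r1 <- greedy_expand(g, seed_edge, cfg)
    r2 <- greedy_expand(g, seed_edge, cfg)
    expect_identical(r1, r2)
    if (is.null(r1)) next
    expect_lte(r1$score,
               brute_force_best(g, seed_edge, gamma = 1) + 1e-12)
  }
})

test_that("find_modules recovers planted modules and stays silent on a
          permuted null", {
  ngene <- 300
  set.seed(2001)                     # fixture stream
  p <- stats::setNames(runif(ngene, 0.01, 1), sprintf("GENE%04d", 1:ngene))
  low <- sample(ngene, 21)
  p[low] <- 10^runif(21, -8, -6)
  ppi <- generate_ppi(p, n_modules = 2L, module_sizes = c(6L, 15L),
                      low_p_max = 1e-4, background_degree = 8, seed = 1L)
  tab <- data.frame(gene = names(p), adjusted_p = unname(p))
  net <- build_weighted_network(ppi$edges, tab)
  cfg <- search_config(n_null = 200L, max_seeds = 100L, seed = 1L)
  mods <- find_modules(net, cfg)
  expect_gte(length(mods), 2L)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  js <- vapply(ppi$truth$module_genes, function(tm)
    max(vapply(mods, function(m) jac(m$members, tm), numeric(1L))),
    numeric(1L))
  expect_true(all(js >= 0.8))
  expect_true(all(vapply(mods, `[[`, numeric(1L),
                         "empirical_p") <= 0.05))
  # empirical p respects the add-one bound
  expect_true(all(vapply(mods, `[[`, numeric(1L), "empirical_p") >=
                    1 / (1 + cfg$n_null)))
  # permuted node p-values: no module should survive
  pn <- stats::setNames(sample(unname(p)), names(p))
  netn <- build_weighted_network(
    generate_ppi(p, n_modules = 0L, module_sizes = integer(0),
                 background_degree = 8, seed = 99L)$edges,
    data.frame(gene = names(pn), adjusted_p = unname(pn)))
  expect_length(find_modules(netn, cfg), 0L)
})

test_that("find_modules output is invariant to node insertion order", {
  set.seed(63)
  p <- stats::setNames(runif(80, 0.01, 1), sprintf("G%03d", 1:80))
  p[sample(80, 10)] <- 1e-7
  ppi <- generate_ppi(p, n_modules = 1L, module_sizes = 8L,
                      low_p_max = 1e-4, seed = 2L)
  tab <- data.frame(gene = names(p), adjusted_p = unname(p))
  cfg <- search_config(n_null = 100L, max_seeds = 30L, seed = 3L)
  net1 <- build_weighted_network(ppi$edges, tab)
  shuf <- sample(nrow(ppi$edges))
  net2 <- build_weighted_network(ppi$edges[shuf, ], tab[sample(80), ])
  m1 <- find_modules(net1, cfg)
  m2 <- find_modules(net2, cfg)
  expect_equal(lapply(m1, `[[`, "members"), lapply(m2, `[[`, "members"))
  expect_equal(vapply(m1, `[[`, numeric(1L), "score"),
               vapply(m2, `[[`, numeric(1L), "score"))
})

test_that("find_modules validates its inputs", {
  g <- toy_network(data.frame(a = "A", b = "B"), 0.5)
  expect_error(find_modules(g, search_config(size_min = 5L)), "few edges")
  expect_error(search_config(n_null = 10L), "n_null")
  expect_error(search_config(size_min = 2L), "size_min")
})
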