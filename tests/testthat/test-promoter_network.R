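ann_fixture <- function() {
  data.frame(
    probe_id = sprintf("cg%d", 1:6),
    gene_symbols = I(list("RNASE4", "RNASE4", c("A1", "B1"), "B1", "C1",
                          character(0))),
    placement = c("TSS200", "Body", "TSS1500", "5'UTR", "TSS200",
                  "intergenic"),
    island_status = rep("Island", 6),
    stringsAsFactors = FALSE)
}

test_that("assign_promoter_probes keeps promoter categories only and is
          monotone in the category set", {
  ann <- ann_fixture()
  m <- assign_promoter_probes(ann)
  expect_setequal_chr(names(m), c("RNASE4", "A1", "B1", "C1"))
  expect_equal(m$RNASE4, "cg1")            # Body probe excluded
  expect_setequal_chr(m$A1, "cg3")         # multi-gene probe in both sets
  expect_setequal_chr(m$B1, "cg3")
  wide <- assign_promoter_probes(ann, c("TSS1500", "TSS200", "5'UTR"))
  for (g in names(m)) {
    expect_true(all(m[[g]] %in% wide[[g]]))
  }
  expect_true("cg4" %in% wide$B1)
  expect_error(assign_promoter_probes(ann, "Promoter"), "category")
})

test_that("promoter_t_tests flattens probe-by-sample vectors and is
          order-invariant", {
  bm <- tiny_betas(n_probes = 6, n_samples = 8, seed = 51)
  rownames(bm$values) <- sprintf("cg%d", 1:6)
  sheet <- data.frame(sample_id = colnames(bm$values),
                      smoker = rep(c(1L, 0L), each = 4),
                      slide = "s1", plate = "p1")
  mapping <- list(G1 = c("cg1", "cg2"), G2 = "cg3")
  res <- promoter_t_tests(bm, sheet, mapping)
  expect_equal(res$n_smoker_values, c(8L, 4L))
  # manual flattening for G1
  vs <- as.vector(bm$values[c("cg1", "cg2"), 1:4])
  vn <- as.vector(bm$values[c("cg1", "cg2"), 5:8])
  expect_equal(res$raw_p[res$gene == "G1"],
               unpaired_t_test(vs, vn)$p, tolerance = 1e-12)
  # permuting probes and samples changes nothing
  bm2 <- beta_matrix(bm$values[sample(6), sample(8)])
  res2 <- promoter_t_tests(bm2, sheet, mapping)
  expect_equal(res$raw_p, res2$raw_p[match(res$gene, res2$gene)])
  # identical groups give p = 1
  flat <- bm
  flat$values["cg3", ] <- 0.3
  res3 <- promoter_t_tests(beta_matrix(flat$values), sheet, mapping)
  expect_equal(res3$raw_p[res3$gene == "G2"], 1)
})

test_that("promoter_t_tests raw p-values are uniform on an i.i.d. null
          cohort", {
  # exchangeable-samples null: no batch offsets, no cell-type contrast,
  # no within-gene baseline dispersion (flattening is conservative when
  # probes of a gene differ in baseline; that limitation is documented)
  panel <- reference_panel_spec(seed = 52L, celltype_delta = 0,
                                n_celltype_probes = 0L)
  spec <- cohort_spec(n_probes = 600L, n_genes = 150L,
                      n_effect_probes = 0L, slide_sd = 0, plate_sd = 0,
                      gene_jitter_sd = 0, seed = 52L)
  co <- generate_cohort(spec, panel)
  mapping <- assign_promoter_probes(co$annotation)
  res <- promoter_t_tests(co$betas, co$sheet, mapping)
  expect_gt(stats::ks.test(res$raw_p, "punif")$p.value, 0.001)
})

test_that("promoter_t_tests detects a gene with shifted promoter probes", {
  panel <- reference_panel_spec(seed = 53L, n_celltype_probes = 40L)
  spec <- cohort_spec(n_probes = 400L, n_genes = 80L, n_effect_probes = 0L,
                      noise_sd = 0.05, seed = 53L)
  co <- generate_cohort(spec, panel)
  mapping <- assign_promoter_probes(co$annotation)
  g <- names(which(lengths(mapping) >= 2))[1L]
  smoker <- co$sheet$smoker[match(colnames(co$betas$values),
                                  co$sheet$sample_id)] == 1L
  v <- co$betas$values
  v[mapping[[g]], smoker] <- pmax(0, v[mapping[[g]], smoker] - 0.1)
  res <- promoter_t_tests(beta_matrix(v), co$sheet, mapping)
  expect_lt(res$adjusted_p[res$gene == g], 1e-4)
})

test_that("edge_weight matches the closed form with its boundary cases", {
  expect_equal(edge_weight(1e-10, 1e-10, 1e-10), 1)
  expect_equal(edge_weight(1, 1, 1e-10), 0)
  expect_equal(edge_weight(1e-5, 1e-5, 1e-10), 0.5)
  # symmetry and monotonicity over random triples
  set.seed(54)
  pm <- 10^runif(10000, -12, -2)
  pi <- 10^(runif(10000) * (0 - log10(pm)) + log10(pm))
  pj <- 10^(runif(10000) * (0 - log10(pm)) + log10(pm))
  w <- edge_weight(pi, pj, pm)
  expect_true(all(w >= 0 & w <= 1))
  expect_equal(w, edge_weight(pj, pi, pm))
  # strictly decreasing in each argument
  eps <- 0.5
  w2 <- edge_weight(pmin(pi * (1 + eps), 1), pj, pm)
  expect_true(all(w2 <= w))
  expect_error(edge_weight(1, 1, 1), "unweightable")
})

test_that("build_weighted_network maps, weights and prunes edges", {
  tab <- data.frame(gene = c("A", "B", "C"),
                    adjusted_p = c(1e-6, 1e-3, 1))
  edges <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "ZZZ"))
  net <- build_weighted_network(edges, tab)
  expect_equal(igraph::ecount(net), 2L)
  expect_equal(igraph::graph_attr(net, "n_dropped_edges"), 1L)
  wAB <- igraph::E(net)$weight[igraph::get_edge_ids(net, c("A", "B"))]
  expect_equal(wAB, edge_weight(1e-6, 1e-3, 1e-6))
  # node attribute is -log10 p'
  expect_equal(igraph::V(net)$neg_log10_p[match("A",
                                                igraph::V(net)$name)], 6)
  # only edges touching the arg-min gene carry weight > 0 when all other
  # p' are 1
  tab2 <- data.frame(gene = c("A", "B", "C"), adjusted_p = c(1e-4, 1, 1))
  net2 <- build_weighted_network(edges, tab2)
  el <- igraph::as_edgelist(net2)
  touches_min <- el[, 1] == "A" | el[, 2] == "A"
  expect_true(all((igraph::E(net2)$weight > 0) == touches_min))
  expect_error(build_weighted_network(data.frame(a = "X", b = "Y"), tab),
               "maps")
})

test_that("weights respond to a global rescaling of p' by the closed form", {
  set.seed(55)
  tab <- data.frame(gene = sprintf("G%02d", 1:20),
                    adjusted_p = 10^runif(20, -8, -0.5))
  edges <- smokeMethNet:::canonicalize_edges(
    sample(tab$gene, 40, replace = TRUE), sample(tab$gene, 40,
                                                 replace = TRUE))
  net1 <- build_weighted_network(edges, tab)
  cfac <- 0.01
  tab2 <- tab
  tab2$adjusted_p <- tab$adjusted_p * cfac
  net2 <- build_weighted_network(edges, tab2)
  p <- stats::setNames(tab$adjusted_p, tab$gene)
  pm <- min(p)
  el <- igraph::as_edgelist(net2)
  expected <- (log(p[el[, 1]] * cfac) + log(p[el[, 2]] * cfac)) /
    (2 * log(pm * cfac))
  expect_equal(igraph::E(net2)$weight, unname(expected), tolerance = 1e-12)
})
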