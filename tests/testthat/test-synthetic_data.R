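test_that("generators are deterministic under a fixed seed", {
  panel <- reference_panel_spec(seed = 5L, n_celltype_probes = 40L)
  spec <- cohort_spec(n_probes = 200L, n_genes = 40L, n_effect_probes = 10L,
                      seed = 5L)
  a <- generate_cohort(spec, panel)
  b <- generate_cohort(spec, panel)
  expect_identical(a$betas$values, b$betas$values)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth, b$truth)
  ra <- generate_reference_panel(panel, n_probes = 200L)
  rb <- generate_reference_panel(panel, n_probes = 200L)
  expect_identical(ra$betas$values, rb$betas$values)
  p <- stats::setNames(runif(60), sprintf("G%03d", 1:60))
  pa <- generate_ppi(p, n_modules = 1L, module_sizes = 5L, low_p_max = 2,
                     seed = 9L)
  pb <- generate_ppi(p, n_modules = 1L, module_sizes = 5L, low_p_max = 2,
                     seed = 9L)
  expect_identical(pa$edges, pb$edges)
  ga <- generate_go_annotation(names(p), n_terms = 10L, seed = 9L)
  gb <- generate_go_annotation(names(p), n_terms = 10L, seed = 9L)
  expect_identical(unclass(ga), unclass(gb))
})

test_that("cohort betas are valid, effects realized at the planted size,
          and structure matches the sheet", {
  panel <- reference_panel_spec(seed = 2L, n_celltype_probes = 60L)
  spec <- cohort_spec(n_probes = 400L, n_genes = 60L, n_effect_probes = 30L,
                      effect_delta_range = c(0.15, 0.15), seed = 2L)
  co <- generate_cohort(spec, panel)
  v <- co$betas$values
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_equal(ncol(v), 111L)
  expect_equal(sum(co$sheet$smoker), 50L)
  expect_setequal_chr(co$sheet$sample_id, colnames(v))
  # planted and cell-type probes are disjoint
  expect_length(intersect(co$truth$effect_probe_ids,
                          co$truth$celltype_probe_ids), 0L)
  # realized group difference at planted (interior-baseline) probes tracks
  # the planted delta
  smoker <- co$sheet$smoker[match(colnames(v), co$sheet$sample_id)] == 1L
  gap <- rowMeans(v[co$truth$effect_probe_ids, smoker, drop = FALSE]) -
    rowMeans(v[co$truth$effect_probe_ids, !smoker, drop = FALSE])
  err <- abs(gap - co$truth$effect_deltas)
  expect_lt(stats::median(err), 0.03)
  expect_true(mean(err < 0.05) > 0.9)
})

test_that("every gene owns a promoter probe and emitted files re-read
          losslessly", {
  panel <- reference_panel_spec(seed = 3L, n_celltype_probes = 30L)
  spec <- cohort_spec(n_probes = 150L, n_genes = 30L, n_effect_probes = 5L,
                      seed = 3L)
  co <- generate_cohort(spec, panel)
  mapping <- assign_promoter_probes(co$annotation)
  expect_setequal_chr(names(mapping), sprintf("GENE%04d", 1:30))
  d <- withr::local_tempdir()
  write_probe_annotation(co$annotation, file.path(d, "ann.tsv"))
  back <- read_probe_annotation(file.path(d, "ann.tsv"))
  expect_equal(back$placement, co$annotation$placement)
  expect_equal(lapply(back$gene_symbols, sort),
               lapply(co$annotation$gene_symbols, toupper))
})

test_that("reference panel plants the promised between-type spread", {
  panel <- reference_panel_spec(seed = 7L, celltype_delta = 0.3)
  ref <- generate_reference_panel(panel, n_probes = 300L)
  v <- ref$betas$values
  bytype <- sapply(split(colnames(v), ref$labels), function(cols)
    rowMeans(v[, cols, drop = FALSE]))
  spread <- apply(bytype, 1L, function(x) max(x) - min(x))
  planted <- rownames(v) %in% ref$truth$celltype_probe_ids
  # planted probes spread near 0.3 (clipping shrinks a few); others tight
  expect_gt(stats::median(spread[planted]), 0.25)
  expect_lt(stats::median(spread[!planted]), 0.1)
})

test_that("generate_ppi plants connected modules among low-p genes and
          validates sizes", {
  set.seed(31)
  p <- stats::setNames(runif(200, 0.01, 1), sprintf("G%03d", 1:200))
  p[sample(200, 25)] <- 1e-7
  ppi <- generate_ppi(p, n_modules = 2L, module_sizes = c(6L, 10L),
                      low_p_max = 1e-4, seed = 4L)
  for (mg in ppi$truth$module_genes) {
    expect_true(all(p[mg] <= 1e-4))
    g <- igraph::graph_from_data_frame(ppi$edges, directed = FALSE)
    sub <- igraph::induced_subgraph(g, match(mg, igraph::V(g)$name))
    expect_true(igraph::is_connected(sub))
  }
  expect_error(generate_ppi(p, n_modules = 1L, module_sizes = 31L),
               "module_sizes")
  expect_error(generate_ppi(stats::setNames(rep(0.5, 30),
                                            sprintf("G%02d", 1:30)),
                            n_modules = 1L, module_sizes = 10L,
                            low_p_max = 1e-4),
               "low-p gene pool")
})

test_that("planted module scores exceed random connected same-size
          subgraphs", {
  set.seed(32)
  p <- stats::setNames(runif(200, 0.01, 1), sprintf("G%03d", 1:200))
  p[sample(200, 12)] <- 10^runif(12, -8, -6)
  ppi <- generate_ppi(p, n_modules = 1L, module_sizes = 10L,
                      low_p_max = 1e-4, background_degree = 8, seed = 6L)
  net <- build_weighted_network(ppi$edges,
                                data.frame(gene = names(p),
                                           adjusted_p = unname(p)))
  mg <- ppi$truth$module_genes[[1L]]
  planted_score <- local_modularity(net, mg)
  # random connected 10-node subgraphs by snowball sampling
  g <- net
  rand_scores <- replicate(100, {
    start <- sample(igraph::V(g)$name, 1)
    mem <- start
    while (length(mem) < 10) {
      nb <- setdiff(names(igraph::neighbors(
        g, sample(mem, 1))), mem)
      if (length(nb) == 0) break
      mem <- c(mem, sample(nb, 1))
    }
    if (length(mem) < 10) NA_real_ else local_modularity(g, mem)
  })
  expect_gt(mean(planted_score > rand_scores, na.rm = TRUE), 0.99)
})

test_that("GO generator plants recoverable enrichment and a flat null", {
  genes <- sprintf("G%03d", 1:300)
  target <- genes[1:12]
  go <- generate_go_annotation(genes, n_terms = 30L,
                               planted = list(target),
                               odds_ratio = 20, seed = 8L)
  res <- enrich(target, genes, go)
  expect_equal(res$term_id[1L], attr(go, "planted_terms")[1L])
  # odds ratio 1 = no enrichment anywhere: raw p roughly uniform
  go0 <- generate_go_annotation(genes, n_terms = 40L,
                                planted = list(target),
                                odds_ratio = 1, seed = 8L)
  res0 <- enrich(target, genes, go0)
  expect_lt(mean(res0$raw_p < 0.05), 0.2)
})
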