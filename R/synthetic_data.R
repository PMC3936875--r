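# Synthetic-data generators emulating the study's inputs: a two-group 450K
# cohort with slide/plate structure and a mixed-cell signal, a purified-cell
# reference panel, a PPI network with planted dense modules among low-p
# genes, and a flat GO annotation with planted enrichment. Ground truth is
# returned alongside every artifact so downstream stages can be scored.

#' Derive a stage-specific RNG seed from a master seed
#'
#' Counter-based fan-out: each named stream gets its own deterministic seed,
#' so regenerating one artifact never shifts another's randomness. Result is
#' kept below 2^31.
#'
#' @param seed Master seed (integer).
#' @param label Stream name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 1299721) %% 2147483647)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Cohort simulation settings
#'
#' Defaults mirror the study design: 50 smokers and 61 non-smokers randomly
#' assigned to 12 slides, planted beta-scale effects spanning the 0.03-0.15
#' group differences seen among top smoking-associated probes.
#'
#' @param n_smokers,n_nonsmokers Group sizes.
#' @param n_probes,n_genes Array and gene-universe sizes.
#' @param n_effect_probes Number of probes with a planted smoking effect.
#' @param effect_delta_range Range of |delta beta| for planted effects,
#'   each in (0, 0.5].
#' @param n_slides,n_plates Technical batch structure.
#' @param slide_sd,plate_sd,noise_sd Additive normal noise scales (beta
#'   units): per probe-by-slide, probe-by-plate, and per cell.
#' @param gene_jitter_sd Within-gene dispersion of probe baselines around
#'   the gene anchor (default 0.05; 0 gives every probe of a gene the same
#'   baseline, the i.i.d. setting used for calibration checks).
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_smokers = 50L, n_nonsmokers = 61L,
                        n_probes = 2000L, n_genes = 300L,
                        n_effect_probes = 60L,
                        effect_delta_range = c(0.03, 0.15),
                        n_slides = 12L, n_plates = 2L,
                        slide_sd = 0.01, plate_sd = 0.01, noise_sd = 0.05,
                        gene_jitter_sd = 0.05, seed = 1L) {
  stopifnot(n_smokers > 0, n_nonsmokers > 0, n_probes > 0, n_genes > 0,
            n_effect_probes >= 0,
            all(effect_delta_range > 0), all(effect_delta_range <= 0.5))
  structure(as.list(environment()), class = "cohort_spec")
}

#' Purified-cell reference panel settings
#'
#' Defaults mirror a five-type sorted-leukocyte panel (CD4+ T, CD8+ T,
#' CD14+ monocytes, CD19+ B, CD56+ NK).
#'
#' @param cell_types Cell-type labels (>= 2).
#' @param n_replicates_per_type Replicates per type.
#' @param n_celltype_probes Probes with planted between-type differences.
#' @param celltype_delta Between-type mean spread (max minus min) at planted
#'   probes, beta units.
#' @param replicate_sd Within-type replicate noise sd.
#' @param seed Master seed.
#' @return A list of class `reference_panel_spec`.
#' @export
reference_panel_spec <- function(cell_types = c("CD4T", "CD8T", "CD14MONO",
                                                "CD19B", "CD56NK"),
                                 n_replicates_per_type = 6L,
                                 n_celltype_probes = 200L,
                                 celltype_delta = 0.3,
                                 replicate_sd = 0.02,
                                 seed = 1L) {
  stopifnot(length(cell_types) >= 2L, n_replicates_per_type >= 2L,
            n_celltype_probes >= 0, celltype_delta >= 0)
  structure(as.list(environment()), class = "reference_panel_spec")
}

probe_ids <- function(n) sprintf("cg%08d", seq_len(n))

# Bimodal baseline betas over (0.05, 0.95), as on real arrays.
baseline_betas <- function(n) {
  lo <- stats::rbeta(n, 2, 10)
  hi <- stats::rbeta(n, 10, 2)
  0.05 + 0.9 * ifelse(stats::runif(n) < 0.5, lo, hi)
}

# Cell-type structure (which probes differ between types, and how): an
# offset matrix (probes x types), zero away from the planted cell-type
# probes. Drawn in its own RNG stream keyed by the panel spec so the
# cohort mixture and the purified panel share the same planted sites even
# though they draw baselines independently.
celltype_structure <- function(n_probes, panel) {
  with_seed(derive_seed(panel$seed, "celltype_structure"), {
    k <- length(panel$cell_types)
    off <- matrix(0, nrow = n_probes, ncol = k,
                  dimnames = list(probe_ids(n_probes), panel$cell_types))
    n_ct <- min(panel$n_celltype_probes, n_probes)
    ct_idx <- sort(sample.int(n_probes, n_ct))
    offs <- seq(-panel$celltype_delta / 2, panel$celltype_delta / 2,
                length.out = k)
    for (i in ct_idx) off[i, ] <- sample(offs)
    list(offsets = off, celltype_probe_idx = ct_idx)
  })
}

# Gene-coherent baselines: probes of one gene scatter tightly around a
# shared anchor, as promoter/gene-body CpGs do on real arrays; unassigned
# probes draw independent bimodal baselines.
gene_anchored_baseline <- function(annotation, jitter_sd = 0.05) {
  n <- nrow(annotation)
  first_gene <- vapply(annotation$gene_symbols,
                       function(g) if (length(g)) g[1L] else "",
                       character(1L))
  base <- baseline_betas(n)
  genes <- unique(first_gene[nzchar(first_gene)])
  anchors <- stats::setNames(baseline_betas(length(genes)), genes)
  hit <- nzchar(first_gene)
  base[hit] <- anchors[first_gene[hit]] +
    stats::rnorm(sum(hit), sd = jitter_sd)
  pmin(pmax(base, 0.05), 0.95)
}

#' Generate a purified-cell reference panel
#'
#' Planted cell-type probes carry a between-type mean spread of
#' `celltype_delta`; all other probes are exchangeable across types.
#'
#' @param panel A [reference_panel_spec()].
#' @param n_probes Number of probes (match the cohort's for downstream use).
#' @return List with `betas` ([beta_matrix()]), `labels` (cell type per
#'   sample) and `truth` (planted cell-type probe ids).
#' @export
generate_reference_panel <- function(panel, n_probes = 2000L) {
  cs <- celltype_structure(n_probes, panel)
  with_seed(derive_seed(panel$seed, "reference_panel"), {
    k <- length(panel$cell_types)
    r <- panel$n_replicates_per_type
    labels <- rep(panel$cell_types, each = r)
    prof <- pmin(pmax(baseline_betas(n_probes) + cs$offsets, 0.02), 0.98)
    vals <- prof[, rep(seq_len(k), each = r), drop = FALSE] +
      matrix(stats::rnorm(n_probes * k * r, sd = panel$replicate_sd),
             nrow = n_probes)
    vals <- pmin(pmax(vals, 0), 1)
    colnames(vals) <- sprintf("%s_rep%d", labels, rep(seq_len(r), times = k))
    rownames(vals) <- probe_ids(n_probes)
    list(betas = beta_matrix(vals),
         labels = stats::setNames(labels, colnames(vals)),
         truth = list(celltype_probe_ids = probe_ids(n_probes)[cs$celltype_probe_idx]))
  })
}

#' Generate a synthetic smoking cohort
#'
#' Each sample is a Dirichlet-weighted mixture of the panel's cell-type
#' profiles plus probe-by-slide and probe-by-plate batch offsets and
#' probe-level noise, clipped to \[0, 1\]. Effect probes (disjoint from the
#' planted cell-type probes) are shifted by a signed delta in smokers only.
#' Probes are annotated to genes such that every gene owns at least one
#' promoter-category probe.
#'
#' @param spec A [cohort_spec()].
#' @param panel A [reference_panel_spec()]; its seed fixes the shared
#'   cell-type profiles.
#' @param dirichlet_conc Dirichlet concentration for per-sample mixing
#'   weights (recycled/truncated to the number of cell types).
#' @return List with `betas`, `sheet`, `annotation` and `truth` (effect
#'   probe ids with signed deltas, cell-type probe ids, true mixing weights).
#' @export
generate_cohort <- function(spec, panel = reference_panel_spec(seed = spec$seed),
                            dirichlet_conc = c(10, 10, 8, 4, 2)) {
  if (spec$n_effect_probes > spec$n_probes) {
    stop("n_effect_probes cannot exceed n_probes")
  }
  cs <- celltype_structure(spec$n_probes, panel)
  k <- ncol(cs$offsets)
  conc <- rep_len(dirichlet_conc, k)
  with_seed(derive_seed(spec$seed, "cohort"), {
    n <- spec$n_smokers + spec$n_nonsmokers
    sample_id <- sprintf("S%04d", seq_len(n))
    smoker <- sample(rep(c(1L, 0L), c(spec$n_smokers, spec$n_nonsmokers)))
    slide <- sprintf("slide%02d", sample.int(spec$n_slides, n, replace = TRUE))
    # plates cross slides (independent assignment), as on real runs where
    # bisulfite plates and array slides are distinct batching layers
    plate <- sprintf("plate%d", sample.int(spec$n_plates, n, replace = TRUE))

    annotation <- random_annotation(spec$n_probes, spec$n_genes)
    jit <- if (is.null(spec$gene_jitter_sd)) 0.05 else spec$gene_jitter_sd
    profiles <- pmin(pmax(gene_anchored_baseline(annotation, jit) +
                            cs$offsets, 0.02), 0.98)

    # Dirichlet mixing weights: normalized gammas, one row per sample
    g <- matrix(stats::rgamma(n * k, shape = rep(conc, each = n)), nrow = n)
    w <- g / rowSums(g)
    vals <- profiles %*% t(w)             # probes x samples

    # batch structure: probe-specific slide and plate offsets
    slide_eff <- matrix(stats::rnorm(spec$n_probes * spec$n_slides,
                                     sd = spec$slide_sd), nrow = spec$n_probes)
    plate_eff <- matrix(stats::rnorm(spec$n_probes * spec$n_plates,
                                     sd = spec$plate_sd), nrow = spec$n_probes)
    vals <- vals + slide_eff[, as.integer(sub("slide", "", slide))] +
      plate_eff[, as.integer(sub("plate", "", plate))]

    # planted smoking effects: disjoint from cell-type probes and placed on
    # interior-baseline probes, where an additive shift survives the [0,1]
    # clipping intact (the strongest real smoking probes are mid-range)
    interior <- rowMeans(profiles) > 0.2 & rowMeans(profiles) < 0.8
    free <- setdiff(which(interior), cs$celltype_probe_idx)
    if (spec$n_effect_probes > length(free)) {
      stop("not enough interior probes free of cell-type structure for the requested effects")
    }
    eff_idx <- sort(sample(free, spec$n_effect_probes))
    delta <- numeric(0)
    if (spec$n_effect_probes > 0L) {
      delta <- stats::runif(spec$n_effect_probes,
                            spec$effect_delta_range[1L],
                            spec$effect_delta_range[2L]) *
        sample(c(-1, 1), spec$n_effect_probes, replace = TRUE)
      vals[eff_idx, smoker == 1L] <- vals[eff_idx, smoker == 1L] + delta
    }

    vals <- vals + matrix(stats::rnorm(length(vals), sd = spec$noise_sd),
                          nrow = spec$n_probes)
    vals <- pmin(pmax(vals, 0), 1)
    dimnames(vals) <- list(probe_ids(spec$n_probes), sample_id)

    sheet <- data.frame(sample_id = sample_id, smoker = smoker,
                        slide = slide, plate = plate,
                        stringsAsFactors = FALSE)
    truth <- list(
      effect_probe_ids = probe_ids(spec$n_probes)[eff_idx],
      effect_deltas = stats::setNames(delta, probe_ids(spec$n_probes)[eff_idx]),
      celltype_probe_ids = probe_ids(spec$n_probes)[cs$celltype_probe_idx],
      mixing_weights = `dimnames<-`(w, list(sample_id, colnames(cs$offsets))))
    list(betas = beta_matrix(vals), sheet = sheet, annotation = annotation,
         truth = truth)
  })
}

# Gene assignment: gene g's first probe is promoter-category (TSS200 or
# TSS1500), guaranteeing >= 1 promoter probe per gene; remaining probes get
# random genes/placements, ~8% intergenic.
random_annotation <- function(n_probes, n_genes) {
  if (n_probes < n_genes) stop("need at least one probe per gene")
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  placement <- character(n_probes)
  gene_of <- character(n_probes)
  placement[seq_len(n_genes)] <- sample(c("TSS200", "TSS1500"), n_genes,
                                        replace = TRUE)
  gene_of[seq_len(n_genes)] <- genes
  rest <- seq.int(n_genes + 1L, length.out = n_probes - n_genes)
  if (length(rest)) {
    inter <- stats::runif(length(rest)) < 0.08
    placement[rest] <- ifelse(inter, "intergenic",
                              sample(PLACEMENT_LEVELS[1:6], length(rest),
                                     replace = TRUE))
    gene_of[rest] <- ifelse(inter, "", sample(genes, length(rest),
                                              replace = TRUE))
  }
  data.frame(
    probe_id = probe_ids(n_probes),
    gene_symbols = I(lapply(gene_of, function(g) if (nzchar(g)) g else character(0))),
    placement = placement,
    island_status = sample(ISLAND_LEVELS, n_probes, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic PPI network with planted modules
#'
#' Planted modules are cliques-with-dropout (connectivity guaranteed by a
#' random spanning path) over genes drawn from the low-p tail of
#' `gene_pvalues`; the background is a configuration-model-style random
#' graph over the remaining genes, and each module is attached to the
#' background by a couple of bridge edges so it is not its own component.
#'
#' @param gene_pvalues Named numeric vector of adjusted gene p-values.
#' @param n_modules Number of planted modules.
#' @param module_sizes Integer vector of module sizes (each in \[4, 30\];
#'   default samples from 5-24, the sub-network size range the search is
#'   tuned for).
#' @param low_p_max Adjusted-p ceiling defining the low-p gene pool modules
#'   are planted in (default 1e-4).
#' @param background_degree Mean background degree.
#' @param edge_keep_prob Within-module edge retention probability.
#' @param seed RNG seed.
#' @return List with `edges` (canonical edge data.frame) and `truth`
#'   (`module_genes`: list of planted member sets).
#' @export
generate_ppi <- function(gene_pvalues, n_modules = 2L, module_sizes = NULL,
                         low_p_max = 1e-4, background_degree = 4,
                         edge_keep_prob = 0.9, seed = 1L) {
  genes <- toupper(names(gene_pvalues))
  with_seed(derive_seed(seed, "ppi"), {
    if (is.null(module_sizes)) {
      module_sizes <- if (n_modules > 0L)
        sample(5:24, n_modules, replace = TRUE) else integer(0)
    }
    stopifnot(length(module_sizes) == n_modules,
              all(module_sizes >= 4L), all(module_sizes <= 30L))
    low_pool <- genes[gene_pvalues <= low_p_max]
    if (sum(module_sizes) > length(low_pool)) {
      stop("planted modules exceed the available low-p gene pool")
    }
    picked <- if (sum(module_sizes) > 0L) sample(low_pool, sum(module_sizes))
              else character(0)
    module_genes <- if (n_modules > 0L)
      split(picked, rep(seq_len(n_modules), times = module_sizes))
    else list()
    a <- character(0); b <- character(0)
    for (mg in module_genes) {
      pairs <- utils::combn(mg, 2L)
      keep <- stats::runif(ncol(pairs)) < edge_keep_prob
      chain <- sample(mg)                       # spanning path => connected
      a <- c(a, pairs[1L, keep], chain[-length(chain)])
      b <- c(b, pairs[2L, keep], chain[-1L])
    }
    bg <- setdiff(genes, picked)
    if (length(bg) >= 2L) {
      deg <- stats::rpois(length(bg), background_degree)
      deg[deg < 1L] <- 1L
      if (sum(deg) %% 2L == 1L) deg[1L] <- deg[1L] + 1L
      g_bg <- igraph::simplify(igraph::sample_degseq(deg,
                                                     method = "configuration"))
      el <- igraph::as_edgelist(g_bg)
      a <- c(a, bg[el[, 1L]]); b <- c(b, bg[el[, 2L]])
      # embed each module in the background with about two bridges per
      # member: the boundary is then large enough that the permutation
      # null cannot rediscover the module on topology alone (the
      # boundary-ratio score of a dangling near-clique is insensitive to
      # the weight level), so discovery hinges on the weight contrast.
      # Bridge targets are distinct, well-connected background genes of
      # unremarkable p-value: a low-p target would inflate the bridge
      # weight, and a poorly connected one would dangle off the module as
      # a near-pendant that a boundary-ratio search would swallow.
      deg_bg <- stats::setNames(igraph::degree(g_bg), bg)
      moderate <- bg[gene_pvalues[match(bg, genes)] >= 
                       stats::median(gene_pvalues)]
      if (length(moderate) < 2L * sum(lengths(module_genes))) moderate <- bg
      well_conn <- moderate[order(-deg_bg[moderate])][seq_len(min(
        max(2L * sum(lengths(module_genes)), ceiling(length(bg) / 4)),
        length(moderate)))]
      for (mg in module_genes) {
        n_br <- 2L * length(mg)
        tgt <- sample(well_conn, min(n_br, length(well_conn)))
        well_conn <- setdiff(well_conn, tgt)
        a <- c(a, rep_len(mg, length(tgt)))
        b <- c(b, tgt)
      }
    }
    list(edges = canonicalize_edges(a, b),
         truth = list(module_genes = module_genes))
  })
}

#' Generate a flat GO-style gene-set collection with planted enrichment
#'
#' Background terms draw members uniformly from `genes`; planted terms
#' over-sample the given target sets at `odds_ratio`.
#'
#' @param genes Universe of gene symbols.
#' @param n_terms Total number of terms.
#' @param planted Named list of gene sets to plant enrichment for (can be
#'   empty).
#' @param odds_ratio Sampling odds for target-set genes in planted terms
#'   (1 = no enrichment).
#' @param term_size_range Range of term sizes.
#' @param seed RNG seed.
#' @return A gene-set collection as from [read_gmt()], with planted term
#'   ids in attribute `planted_terms`.
#' @export
generate_go_annotation <- function(genes, n_terms = 50L, planted = list(),
                                   odds_ratio = 20, term_size_range = c(10L, 50L),
                                   seed = 1L) {
  genes <- toupper(genes)
  with_seed(derive_seed(seed, "go"), {
    sizes <- sample(term_size_range[1L]:term_size_range[2L], n_terms,
                    replace = TRUE)
    sets <- vector("list", n_terms)
    ids <- sprintf("GO:%07d", seq_len(n_terms))
    planted_ids <- character(0)
    for (i in seq_len(n_terms)) {
      if (i <= length(planted)) {
        target <- toupper(planted[[i]])
        wts <- ifelse(genes %in% target, odds_ratio, 1)
        sz <- max(sizes[i], length(target))
        sets[[i]] <- sample(genes, min(sz, length(genes)), prob = wts)
        planted_ids <- c(planted_ids, ids[i])
      } else {
        sets[[i]] <- sample(genes, min(sizes[i], length(genes)))
      }
    }
    names(sets) <- ids
    attr(sets, "term_names") <- stats::setNames(
      sprintf("synthetic category %d", seq_len(n_terms)), ids)
    attr(sets, "planted_terms") <- planted_ids
    sets
  })
}
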