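# Synthetic-data generators with planted ground truth. They emulate the
# study design every stage of the pipeline consumes — a 4-group (plus
# pooled-QC) serum peak table with differential metabolites that recover
# under treatment, target-database snapshots with a planted critical-target
# overlap wired as PPI hubs, and a qPCR Ct table with planted group effects
# — so the whole workflow is testable offline with known answers.

#' Simulation configuration for the synthetic peak table
#'
#' Defaults mirror the emulated study design: 8 animals per biological
#' group (N, D, P, H), pooled QC injections, lognormal feature baselines
#' spanning three decades, a 3-fold planted disease effect of which the
#' high-dose treatment group recovers 80% (the reference-drug group P
#' recovers half as much, so the treated group H is the better responder
#' and is the one analyzed downstream), multiplicative noise at 15% CV, and
#' left-censoring of the lowest 5% of intensities at a shared detection
#' limit.
#'
#' @param n_per_group Samples per biological group (N, D, P, H).
#' @param n_qc Pooled QC injections.
#' @param n_features Total features.
#' @param n_planted Differential (planted) features.
#' @param planted_fold_change Multiplicative D-vs-N effect (> 1 up, < 1
#'   down).
#' @param recovery_fraction Fraction of the D-shift reversed in group H
#'   (0-1); group P reverses half this.
#' @param cv_noise Lognormal coefficient of variation of replicate noise.
#' @param detection_limit_quantile Fraction of low intensities censored to
#'   missing at a shared (global-quantile) detection limit.
#' @param rt_range Retention-time range of the gradient, minutes.
#' @param seed RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_group = 8, n_qc = 6, n_features = 500,
                       n_planted = 10, planted_fold_change = 3,
                       recovery_fraction = 0.8, cv_noise = 0.15,
                       detection_limit_quantile = 0.05,
                       rt_range = c(0, 25), seed = 1) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_qc = as.integer(n_qc),
    n_features = as.integer(n_features), n_planted = as.integer(n_planted),
    planted_fold_change = planted_fold_change,
    recovery_fraction = recovery_fraction, cv_noise = cv_noise,
    detection_limit_quantile = detection_limit_quantile,
    rt_range = rt_range, seed = as.integer(seed)
  )
  if (cfg$n_planted > cfg$n_features) abort("n_planted must be <= n_features")
  if (cfg$recovery_fraction < 0 || cfg$recovery_fraction > 1) {
    abort("recovery_fraction must be in [0, 1]")
  }
  if (cfg$n_per_group < 1 || cfg$n_qc < 1 || cfg$n_features < 1) {
    abort("all counts must be >= 1")
  }
  if (cfg$planted_fold_change <= 0) abort("planted_fold_change must be > 0")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic feature table with planted truth
#'
#' Feature baselines are lognormal with medians drawn log-uniformly over
#' three decades; replicate noise is multiplicative at `cv_noise`. Planted
#' features are multiplied by `planted_fold_change` in group D; groups H
#' and P reverse the log-scale shift by `recovery_fraction` and half of it,
#' respectively. QC samples are drawn around the pooled group mean with 5%
#' CV. Intensities below the global `detection_limit_quantile` are censored
#' to missing. Planted features elute inside the 2-20 min analysis window
#' (decoys span the whole gradient), and the first `min(n_planted,
#' nrow(library))` planted features receive the m/z of a library compound's
#' adduct within a few ppm so annotation succeeds; decoy m/z are redrawn
#' away from library adducts.
#'
#' @param config A [sim_config()].
#' @param library A [compound_library()] used for planted m/z (default
#'   [demo_compound_library()]).
#' @return List with `table` (a [feature_table()]) and `truth` (planted
#'   feature ids, per-feature direction, feature -> compound annotation
#'   map).
#' @export
generate_feature_table <- function(config = sim_config(),
                                   library = demo_compound_library()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_features
  npg <- config$n_per_group
  fc <- config$planted_fold_change
  ids <- sprintf("F%04d", seq_len(n))
  planted <- if (config$n_planted > 0) ids[seq_len(config$n_planted)] else character()

  baseline <- 10^runif(n, 3, 6)
  sigma <- sqrt(log(1 + config$cv_noise^2))
  sigma_qc <- sqrt(log(1 + 0.05^2))

  shift <- rep(1, n)
  shift[ids %in% planted] <- fc
  mean_n <- baseline
  mean_d <- baseline * shift
  mean_h <- baseline * shift^(1 - config$recovery_fraction)
  mean_p <- baseline * shift^(1 - config$recovery_fraction / 2)

  draw_group <- function(means, k, s) {
    matrix(
      rep(means, k) * exp(rnorm(n * k, sd = s)),
      nrow = n, ncol = k
    )
  }
  xn <- draw_group(mean_n, npg, sigma)
  xd <- draw_group(mean_d, npg, sigma)
  xp <- draw_group(mean_p, npg, sigma)
  xh <- draw_group(mean_h, npg, sigma)
  pooled <- (mean_n + mean_d + mean_p + mean_h) / 4
  xqc <- draw_group(pooled, config$n_qc, sigma_qc)
  x <- cbind(xn, xd, xp, xh, xqc)

  sample_meta <- tibble::tibble(
    sample_id = c(
      sprintf("N%02d", seq_len(npg)), sprintf("D%02d", seq_len(npg)),
      sprintf("P%02d", seq_len(npg)), sprintf("H%02d", seq_len(npg)),
      sprintf("QC%02d", seq_len(config$n_qc))
    ),
    group = c(rep(c("N", "D", "P", "H"), each = npg), rep("QC", config$n_qc))
  )

  # retention times: planted metabolites elute mid-gradient (inside the
  # 2-20 min analysis window); decoys span the full gradient
  rt <- runif(n, config$rt_range[1], config$rt_range[2])
  win <- c(max(config$rt_range[1], 2), min(config$rt_range[2], 20))
  rt[ids %in% planted] <- runif(length(planted), win[1], win[2])

  # m/z: annotated planted features sit on library adducts (+- 5 ppm);
  # everything else is kept > 30 ppm away from any library adduct
  mz <- runif(n, 100, 1200)
  lib_mz <- library$theoretical_mz
  too_close <- function(v) {
    vapply(v, function(m) any(abs(m - lib_mz) / lib_mz * 1e6 < 30), logical(1))
  }
  redraw <- too_close(mz)
  while (any(redraw)) {
    mz[redraw] <- runif(sum(redraw), 100, 1200)
    redraw <- too_close(mz)
  }
  n_annot <- min(length(planted), nrow(library))
  annotation <- tibble::tibble(
    feature_id = character(), compound_id = character(), name = character()
  )
  if (n_annot > 0) {
    idx <- match(planted[seq_len(n_annot)], ids)
    mz[idx] <- library$theoretical_mz[seq_len(n_annot)] *
      (1 + runif(n_annot, -5, 5) / 1e6)
    annotation <- tibble::tibble(
      feature_id = planted[seq_len(n_annot)],
      compound_id = library$compound_id[seq_len(n_annot)],
      name = library$name[seq_len(n_annot)]
    )
  }

  # global-quantile left-censoring at a shared detection limit
  limit <- quantile(x, config$detection_limit_quantile, names = FALSE)
  x[x < limit] <- NA

  table <- feature_table(
    x,
    feature_meta = tibble::tibble(feature_id = ids, mz = mz, rt = rt),
    sample_meta = sample_meta
  )
  truth <- list(
    differential_feature_ids = planted,
    direction_per_feature = setNames(
      rep(if (fc > 1) "up" else "down", length(planted)), planted
    ),
    annotation = annotation,
    detection_limit = limit
  )
  list(table = table, truth = truth)
}

#' Generate target-database snapshots with a planted critical overlap
#'
#' Planted critical targets appear in all three target lists, carry disease
#' relevance scores above 20, and are wired as hubs of the PPI edge list
#' (a mutual clique plus spokes to the common decoys) so centrality
#' screening retains them. Decoy targets appear in only one or two lists or
#' as low-degree periphery. Each library compound is assigned three planted
#' criticals round-robin, so every critical is covered by several
#' metabolites. Default list sizes mirror a realistic funnel: 243 component
#' targets, 990 disease targets (common set 62), 88 metabolite targets.
#'
#' @param n_component_targets,n_disease_targets,n_metabolite_targets List
#'   sizes.
#' @param n_planted_critical Planted critical targets (in all three lists).
#' @param n_common_decoys Decoys shared by the component and disease lists
#'   only (they populate the common PPI network as periphery).
#' @param seed RNG seed.
#' @param library Compound library naming the metabolites of the
#'   metabolite-target list.
#' @return List with tibbles `component_targets`, `disease_targets`,
#'   `metabolite_targets`, `ppi_edges`, and `truth`
#'   (`planted_critical_targets`).
#' @export
generate_target_databases <- function(n_component_targets = 243,
                                      n_disease_targets = 990,
                                      n_metabolite_targets = 88,
                                      n_planted_critical = 6,
                                      n_common_decoys = 56,
                                      seed = 1,
                                      library = demo_compound_library()) {
  stopifnot(
    n_planted_critical <= n_component_targets,
    n_planted_critical <= n_disease_targets,
    n_planted_critical <= n_metabolite_targets,
    n_planted_critical + n_common_decoys <= n_component_targets,
    n_planted_critical + n_common_decoys <= n_disease_targets
  )
  set.seed(seed)
  k <- n_planted_critical
  crit <- if (k > 0) sprintf("CT%02d", seq_len(k)) else character()
  common_decoys <- if (n_common_decoys > 0) {
    sprintf("CD%03d", seq_len(n_common_decoys))
  } else {
    character()
  }
  n_co <- n_component_targets - k - n_common_decoys
  n_dd <- n_disease_targets - k - n_common_decoys
  comp_only <- if (n_co > 0) sprintf("CO%03d", seq_len(n_co)) else character()
  dis_only <- if (n_dd > 0) sprintf("DD%03d", seq_len(n_dd)) else character()
  n_md <- n_metabolite_targets - k
  met_only <- if (n_md > 0) sprintf("MD%03d", seq_len(n_md)) else character()

  component_targets <- tibble::tibble(symbol = c(crit, common_decoys, comp_only))
  disease_targets <- tibble::tibble(
    symbol = c(crit, common_decoys, dis_only),
    relevance_score = round(c(
      runif(k, 40, 95),            # planted: comfortably above the filter
      runif(n_common_decoys, 20.5, 90),  # common decoys survive the filter
      runif(n_dd, 1, 90)           # disease-only decoys: mixed relevance
    ), 2)
  )

  # metabolite -> target map: each library compound covers 3 planted
  # criticals round-robin; decoy targets hang off random compounds
  met_rows <- list()
  if (k > 0 && nrow(library) > 0) {
    met_rows$crit <- purrr::map_dfr(seq_len(nrow(library)), function(i) {
      sel <- ((i - 1 + 0:2) %% k) + 1
      tibble::tibble(symbol = crit[unique(sel)], metabolite = library$name[i])
    })
  }
  if (n_md > 0) {
    met_rows$dec <- tibble::tibble(
      symbol = met_only,
      metabolite = sample(library$name, n_md, replace = TRUE)
    )
  }
  metabolite_targets <- if (length(met_rows) > 0) {
    dplyr::bind_rows(met_rows)
  } else {
    tibble::tibble(symbol = character(), metabolite = character())
  }

  # PPI wiring over the common (component & disease) targets: planted
  # criticals form a clique and collect spokes from the decoy periphery
  edges <- list()
  if (k > 1) {
    pairs <- utils::combn(crit, 2)
    edges$clique <- tibble::tibble(
      from = pairs[1, ], to = pairs[2, ],
      score = round(runif(ncol(pairs), 0.7, 0.99), 3)
    )
  }
  if (k > 0 && n_common_decoys > 0) {
    hub1 <- crit[((seq_len(n_common_decoys) - 1) %% k) + 1]
    hub2 <- crit[(seq_len(n_common_decoys) %% k) + 1]
    edges$spokes <- tibble::tibble(
      from = rep(common_decoys, 2), to = c(hub1, hub2),
      score = round(runif(2 * n_common_decoys, 0.5, 0.95), 3)
    )
    # sparse low-confidence periphery edges (some below the score cutoff)
    n_extra <- max(1L, n_common_decoys %/% 4L)
    edges$extra <- tibble::tibble(
      from = sample(common_decoys, n_extra, replace = TRUE),
      to = sample(common_decoys, n_extra, replace = TRUE),
      score = round(runif(n_extra, 0.15, 0.9), 3)
    ) |> dplyr::filter(.data$from != .data$to)
  }
  ppi_edges <- if (length(edges) > 0) {
    dplyr::bind_rows(edges)
  } else {
    tibble::tibble(from = character(), to = character(), score = numeric())
  }

  list(
    component_targets = component_targets,
    disease_targets = disease_targets,
    metabolite_targets = metabolite_targets,
    ppi_edges = ppi_edges,
    truth = list(planted_critical_targets = crit)
  )
}

#' Generate a gene-set collection around the synthetic targets
#'
#' Builds pathway-style terms over the symbols of the synthetic databases:
#' a few "signal" terms concentrated on the planted critical targets plus
#' background terms of random decoys, for exercising over-representation
#' analysis.
#'
#' @param databases Output of [generate_target_databases()].
#' @param n_terms Total number of terms.
#' @param seed RNG seed.
#' @return A [gene_set_collection()].
#' @export
generate_gene_sets <- function(databases, n_terms = 10, seed = 1) {
  set.seed(seed)
  crit <- databases$truth$planted_critical_targets
  universe <- unique(c(
    databases$component_targets$symbol, databases$disease_targets$symbol,
    databases$metabolite_targets$symbol
  ))
  decoys <- setdiff(universe, crit)
  sets <- list()
  n_signal <- min(3L, n_terms)
  for (i in seq_len(n_signal)) {
    # round-robin so every planted critical is covered by some term
    own <- if (length(crit) > 0) crit[seq(i, length(crit), by = n_signal)] else character()
    sets[[sprintf("PATH%02d", i)]] <- unique(c(
      own, sample(crit, min(2, length(crit))), sample(decoys, 8)
    ))
  }
  for (i in seq_len(n_terms - n_signal)) {
    sets[[sprintf("PATH%02d", n_signal + i)]] <- sample(decoys, sample(8:20, 1))
  }
  gene_set_collection(sets, background = universe)
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene Ct is stable across groups; responsive genes are shifted
#' by `planted_effect_dct` cycles in group D and moved back toward the
#' normal level in group H by `retracement_fraction` (group P, when
#' present, by half of it). Gaussian replicate noise of `noise_sd` cycles
#' is added everywhere.
#'
#' @param genes Gene symbols, including the reference gene.
#' @param groups Group labels to simulate (default N, D, H).
#' @param n_per_group Samples per group.
#' @param planted_effect_dct Cycle shift of responsive genes in group D
#'   (negative = earlier amplification = higher expression).
#' @param retracement_fraction Fraction of the D-shift reversed in H (0-1).
#' @param responsive_genes Genes carrying the planted effect (default: all
#'   non-reference genes).
#' @param reference_gene Normalization gene (must be in `genes`).
#' @param noise_sd Replicate noise SD in cycles.
#' @param seed RNG seed.
#' @return A [ct_table()].
#' @export
generate_ct_table <- function(genes, groups = c("N", "D", "H"),
                              n_per_group = 8, planted_effect_dct = -1,
                              retracement_fraction = 0.8,
                              responsive_genes = NULL,
                              reference_gene = "ACTB", noise_sd = 0.1,
                              seed = 1) {
  if (!reference_gene %in% genes) abort("reference gene must be in genes")
  set.seed(seed)
  responsive_genes <- responsive_genes %||% setdiff(genes, reference_gene)
  base_ct <- setNames(runif(length(genes), 20, 26), genes)
  base_ct[reference_gene] <- 17
  shift_for <- function(gene, group) {
    if (!gene %in% responsive_genes) return(0)
    switch(group,
      D = planted_effect_dct,
      H = planted_effect_dct * (1 - retracement_fraction),
      P = planted_effect_dct * (1 - retracement_fraction / 2),
      0
    )
  }
  df <- tidyr::expand_grid(
    gene = genes, group = groups, rep = seq_len(n_per_group)
  ) |>
    dplyr::mutate(
      sample = sprintf("%s%02d", .data$group, .data$rep),
      ct = purrr::map2_dbl(.data$gene, .data$group,
                           ~ base_ct[[.x]] + shift_for(.x, .y)) +
        rnorm(dplyr::n(), sd = noise_sd)
    ) |>
    dplyr::select("gene", "sample", "group", "ct")
  ct_table(df, reference_gene = reference_gene)
}

#' Write every pipeline input to a directory
#'
#' Generates the peak table, target databases, gene sets and Ct table for
#' one configuration and writes them in the pipeline's interchange formats
#' (TSV/GMT), together with a JSON manifest recording the configuration and
#' the planted truth.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @param seed Seed for the non-peak-table generators (default: the
#'   config's seed).
#' @return Invisibly, a named list of the written paths plus the truth.
#' @export
write_pipeline_inputs <- function(dir, config = sim_config(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  library <- demo_compound_library()
  ft <- generate_feature_table(config, library = library)
  db <- generate_target_databases(seed = derive_seed(seed, 1), library = library)
  gs <- generate_gene_sets(db, seed = derive_seed(seed, 2))
  ct <- generate_ct_table(
    genes = c(db$truth$planted_critical_targets, "ACTB"),
    seed = derive_seed(seed, 3)
  )
  paths <- list(
    feature_table = file.path(dir, "feature_table.tsv"),
    compound_library = file.path(dir, "compound_library.tsv"),
    component_targets = file.path(dir, "component_targets.tsv"),
    disease_targets = file.path(dir, "disease_targets.tsv"),
    metabolite_targets = file.path(dir, "metabolite_targets.tsv"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    ct_table = file.path(dir, "ct_table.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_feature_table(ft$table, paths$feature_table)
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(library), -"adduct", -"theoretical_mz") |>
      dplyr::distinct() |>
      dplyr::mutate(adducts = "[M+H]+"),
    paths$compound_library
  )
  readr::write_tsv(db$component_targets, paths$component_targets)
  readr::write_tsv(db$disease_targets, paths$disease_targets)
  readr::write_tsv(db$metabolite_targets, paths$metabolite_targets)
  readr::write_tsv(db$ppi_edges, paths$ppi_edges)
  write_gmt(gs, paths$gene_sets)
  readr::write_tsv(as.data.frame(ct), paths$ct_table)
  truth <- c(ft$truth[c("differential_feature_ids", "direction_per_feature")],
             db$truth,
             list(annotation = ft$truth$annotation))
  write_manifest(
    list(config = unclass(config), truth = truth, files = paths),
    paths$manifest
  )
  invisible(c(paths, list(truth = truth)))
}
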