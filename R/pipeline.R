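# Stage orchestration: each stage reads its input artifacts from disk,
# runs the corresponding module functions, and writes plain-text artifacts,
# so a full analysis is reproducible from a single config (YAML-loadable)
# and re-runs are byte-identical for identical seeds.

#' Pipeline configuration
#'
#' Collects every path and threshold of the workflow. Defaults are the
#' published screening thresholds: RT window 2-20 min, 50% detection rate,
#' VIP > 1.5, raw p < 0.05, FDR < 0.05, relevance score > 20, edge score
#' >= 0.4, degree > 11, betweenness > 0.00533, closeness > 0.5236, 999
#' permutations, 7-fold cross-validation.
#'
#' @param input_dir Directory holding (or receiving, for the simulate
#'   stage) the pipeline inputs.
#' @param out_dir Directory for artifacts.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param sim A [sim_config()] for the simulate stage (default uses
#'   `seed`).
#' @param rt_min,rt_max,min_detection_rate Preprocessing thresholds.
#' @param scaling,folds,n_perm Discriminant-model parameters.
#' @param vip_min,p_max,fdr_max Screening-cascade thresholds.
#' @param tol_ppm Annotation tolerance (ppm).
#' @param relevance_min,min_edge_score,deg_min,bc_min,cc_min Network
#'   thresholds.
#' @param calibrator_group,reference_gene qPCR settings.
#' @param mva_groups Groups entering the discriminant model.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1,
                            sim = sim_config(seed = seed),
                            rt_min = 2, rt_max = 20, min_detection_rate = 0.5,
                            scaling = "pareto", folds = 7, n_perm = 999,
                            mva_groups = c("N", "D", "H"),
                            vip_min = 1.5, p_max = 0.05, fdr_max = 0.05,
                            tol_ppm = 10, relevance_min = 20,
                            min_edge_score = 0.4, deg_min = 11,
                            bc_min = 0.00533, cc_min = 0.5236,
                            calibrator_group = "N", reference_gene = "ACTB") {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of [pipeline_config()] fields (`sim` may be a
#'   nested map of [sim_config()] fields).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$sim)) vals$sim <- do.call(sim_config, vals$sim)
  do.call(pipeline_config, vals)
}

artifact_path <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, stage) {
  p <- artifact_path(config, name)
  if (!file.exists(p)) {
    abort(sprintf("missing artifact '%s'; run stage '%s' first", name, stage))
  }
  p
}

input_path <- function(config, name, stage = "simulate") {
  p <- file.path(config$input_dir, name)
  if (!file.exists(p)) {
    abort(sprintf("missing input '%s'; run stage '%s' first or point input_dir at existing data",
                  name, stage))
  }
  p
}

stage_simulate <- function(config) {
  write_pipeline_inputs(config$input_dir, config$sim)
}

stage_preprocess <- function(config) {
  table <- read_feature_table(input_path(config, "feature_table.tsv"))
  processed <- table |>
    filter_by_rt(config$rt_min, config$rt_max) |>
    filter_by_detection(config$min_detection_rate) |>
    impute_half_minimum()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(processed, artifact_path(config, "processed_raw.tsv"))
  readr::write_tsv(processing_log(processed),
                   artifact_path(config, "processing_log.tsv"))
  processed
}

read_processed <- function(config) {
  read_feature_table(require_artifact(config, "processed_raw.tsv", "preprocess"))
}

stage_mva <- function(config) {
  processed <- read_processed(config)
  logt <- log10_transform(processed)
  model <- opls_da(logt, groups = config$mva_groups,
                   scaling = config$scaling, folds = config$folds)
  perm <- permutation_test(model, n_perm = config$n_perm,
                           seed = derive_seed(config$seed, 11))
  scores <- pca_scores(scale_features(logt, config$scaling), k = 2)
  readr::write_tsv(tidy(model), artifact_path(config, "vip.tsv"))
  readr::write_tsv(opls_scores(model), artifact_path(config, "opls_scores.tsv"))
  readr::write_tsv(scores, artifact_path(config, "pca_scores.tsv"))
  readr::write_tsv(tidy(perm), artifact_path(config, "permutations.tsv"))
  jsonlite::write_json(
    c(as.list(glance(model)), as.list(glance(perm))),
    artifact_path(config, "model.json"),
    auto_unbox = TRUE, digits = NA
  )
  list(model = model, permutation = perm)
}

stage_screen <- function(config) {
  processed <- read_processed(config)
  vip_tbl <- readr::read_tsv(require_artifact(config, "vip.tsv", "mva"),
                             show_col_types = FALSE)
  records <- screen_cascade(
    processed, vip_tbl[, c("feature_id", "vip")],
    vip_min = config$vip_min, p_max = config$p_max, fdr_max = config$fdr_max
  )
  readr::write_tsv(tibble::as_tibble(records),
                   artifact_path(config, "screen_records.tsv"))
  readr::write_tsv(attr(records, "log"),
                   artifact_path(config, "screen_log.tsv"))
  records
}

stage_annotate <- function(config) {
  processed <- read_processed(config)
  library <- read_compound_library(input_path(config, "compound_library.tsv"))
  records <- readr::read_tsv(
    require_artifact(config, "screen_records.tsv", "screen"),
    show_col_types = FALSE
  )
  hits <- match_features(processed, library, tol_ppm = config$tol_ppm)
  report <- screen_report(records, hits, processed)
  readr::write_tsv(hits, artifact_path(config, "annotation_hits.tsv"))
  readr::write_tsv(report, artifact_path(config, "screened_metabolites.tsv"))
  report
}

stage_network <- function(config) {
  component <- read_targets(input_path(config, "component_targets.tsv"), "component")
  disease <- read_targets(input_path(config, "disease_targets.tsv"), "disease")
  metab <- read_targets(input_path(config, "metabolite_targets.tsv"), "metabolite")
  edges <- read_ppi_edges(input_path(config, "ppi_edges.tsv"))
  screened <- readr::read_tsv(
    require_artifact(config, "screened_metabolites.tsv", "annotate"),
    show_col_types = FALSE
  )
  disease_kept <- filter_disease_targets(disease, config$relevance_min)
  common <- intersect_targets(component, disease_kept)
  g <- build_ppi(edges, node_whitelist = common,
                 min_edge_score = config$min_edge_score)
  cent <- centralities(g)
  critical <- screen_critical_targets(cent, config$deg_min, config$bc_min,
                                      config$cc_min)
  screened_names <- unique(stats::na.omit(screened$name))
  met_screened <- metab[metab$metabolite %in% screened_names, , drop = FALSE]
  final <- integrate_metabolite_targets(critical, met_screened)
  readr::write_tsv(cent, artifact_path(config, "centralities.tsv"))
  writeLines(critical, artifact_path(config, "critical_targets.txt"))
  readr::write_tsv(final, artifact_path(config, "final_targets.tsv"))
  export_network(g, artifact_path(config, "ppi_network.sif"), "sif")
  export_network(g, artifact_path(config, "ppi_network.graphml"), "graphml",
                 annotations = cent)
  list(
    common = common, graph = g, centralities = cent, critical = critical,
    final = final,
    funnel = tibble::tibble(
      stage = c("component_targets", "disease_targets", "common_targets",
                "critical_targets", "metabolite_targets", "final_targets"),
      count = c(nrow(component), nrow(disease_kept), length(common),
                length(critical), length(unique(metab$symbol)), nrow(final))
    )
  )
}

stage_enrich <- function(config) {
  final <- readr::read_tsv(
    require_artifact(config, "final_targets.tsv", "network"),
    show_col_types = FALSE
  )
  collection <- read_gmt(input_path(config, "gene_sets.gmt"))
  ora <- hypergeometric_ora(final$symbol, collection)
  readr::write_tsv(ora, artifact_path(config, "enrichment.tsv"))
  ora
}

stage_qpcr <- function(config) {
  ct <- read_ct_table(input_path(config, "ct_table.tsv"),
                      reference_gene = config$reference_gene)
  re <- delta_delta_ct(ct, calibrator_group = config$calibrator_group)
  cmp <- expression_compare(re, groups = c("N", "D"))
  ret <- retracement_check(re)
  summary <- dplyr::left_join(
    ret, dplyr::select(cmp, "gene", p_nd = "p_value", mark_nd = "mark"),
    by = "gene"
  )
  readr::write_tsv(tidy(re), artifact_path(config, "relative_expression.tsv"))
  readr::write_tsv(summary, artifact_path(config, "qpcr_summary.tsv"))
  list(expression = re, summary = summary)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `preprocess`, `mva`, `screen`, `annotate`,
#' `network`, `enrich`, `qpcr`, `report`. Each writes its artifacts under
#' `config$out_dir`; a stage whose prerequisites are missing stops with a
#' message naming the stage to run first.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(name, config) {
  stages <- list(
    simulate = stage_simulate, preprocess = stage_preprocess,
    mva = stage_mva, screen = stage_screen, annotate = stage_annotate,
    network = stage_network, enrich = stage_enrich, qpcr = stage_qpcr,
    report = stage_report
  )
  if (!name %in% names(stages)) {
    abort(sprintf("unknown stage '%s' (expected one of %s)",
                  name, paste(names(stages), collapse = ", ")))
  }
  invisible(stages[[name]](config))
}

stage_report <- function(config) {
  model <- jsonlite::read_json(require_artifact(config, "model.json", "mva"))
  plog <- readr::read_tsv(require_artifact(config, "processing_log.tsv", "preprocess"),
                          show_col_types = FALSE)
  slog <- readr::read_tsv(require_artifact(config, "screen_log.tsv", "screen"),
                          show_col_types = FALSE)
  screened <- readr::read_tsv(
    require_artifact(config, "screened_metabolites.tsv", "annotate"),
    show_col_types = FALSE
  )
  final <- readr::read_tsv(require_artifact(config, "final_targets.tsv", "network"),
                           show_col_types = FALSE)
  critical <- readLines(require_artifact(config, "critical_targets.txt", "network"))
  qpcr <- readr::read_tsv(require_artifact(config, "qpcr_summary.tsv", "qpcr"),
                          show_col_types = FALSE)
  enr <- readr::read_tsv(require_artifact(config, "enrichment.tsv", "enrich"),
                         show_col_types = FALSE)
  fmt_tbl <- function(df) {
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c(
    "# Integrated screening report", "",
    "## Feature preprocessing", fmt_tbl(plog), "",
    sprintf("## Discriminant model (R2X %.3f, R2Y %.3f, Q2 %.3f; %s)",
            model$r2x, model$r2y, model$q2,
            if (isTRUE(model$valid)) "permutation test passed"
            else "permutation test failed"),
    "", "## Screening cascade", fmt_tbl(slog), "",
    sprintf("Screened metabolites: %d", nrow(screened)), "",
    "## Target funnel",
    sprintf("- critical targets: %d (%s)", length(critical),
            paste(critical, collapse = ", ")),
    sprintf("- final targets: %d (%s)", nrow(final),
            paste(final$symbol, collapse = ", ")), "",
    "## Enrichment (top terms)",
    fmt_tbl(utils::head(enr[, c("term", "overlap", "p_value", "q_value")], 5)),
    "", "## qPCR verification", fmt_tbl(qpcr)
  )
  writeLines(lines, artifact_path(config, "report.md"))
  invisible(lines)
}

#' Run the whole pipeline
#'
#' Executes every stage in dependency order and writes a markdown report
#' with the stage funnel. Re-running with an identical configuration and
#' seed reproduces the artifacts byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param simulate Run the simulate stage first (set `FALSE` when
#'   `input_dir` already holds real inputs).
#' @return Named list of stage results (model, screen records, network
#'   funnel, final targets, enrichment, qPCR summary).
#' @export
run_all <- function(config, simulate = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (simulate) run_stage("simulate", config)
  preprocess <- run_stage("preprocess", config)
  mva <- run_stage("mva", config)
  screen <- run_stage("screen", config)
  annotate <- run_stage("annotate", config)
  network <- run_stage("network", config)
  enrich <- run_stage("enrich", config)
  qpcr <- run_stage("qpcr", config)
  run_stage("report", config)
  list(
    processed = preprocess, model = mva$model, permutation = mva$permutation,
    screen = screen, screened = annotate, network = network,
    final_targets = network$final, enrichment = enrich, qpcr = qpcr
  )
}
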