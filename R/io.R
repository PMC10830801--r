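# Readers/writers for the plain-text interchange formats the pipeline uses.
# Peak tables are TSV with columns feature_id / mz / rt then one column per
# sample; sample metadata travels in a separate two-column TSV. Missing
# intensities are empty cells or "NA".

#' Write a feature table to TSV
#'
#' @param table A [feature_table()].
#' @param path Peak-table TSV path (feature_id, mz, rt, one column/sample).
#' @param sample_path Sample-metadata TSV path (sample_id, group); default
#'   `<path>` with a `.samples.tsv` suffix.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path,
                                sample_path = paste0(path, ".samples.tsv")) {
  stopifnot(inherits(table, "feature_table"))
  wide <- dplyr::bind_cols(
    table$feature_meta[, c("feature_id", "mz", "rt")],
    tibble::as_tibble(table$intensities)
  )
  readr::write_tsv(wide, path, na = "NA")
  readr::write_tsv(table$sample_meta[, c("sample_id", "group")], sample_path)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' @param path Peak-table TSV written by [write_feature_table()].
#' @param sample_path Sample-metadata TSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, sample_path = paste0(path, ".samples.tsv")) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  samples <- readr::read_tsv(sample_path, show_col_types = FALSE)
  meta_cols <- c("feature_id", "mz", "rt")
  stopifnot(all(meta_cols %in% names(wide)))
  intens <- as.matrix(wide[, setdiff(names(wide), meta_cols), drop = FALSE])
  feature_table(intens, wide[, meta_cols], samples)
}

#' Read a target list
#'
#' Expects a TSV with a `symbol` column and, for disease targets, a
#' `relevance_score` column. Symbols are canonicalized (trimmed, uppercased)
#' and duplicates collapsed keeping the maximum score.
#'
#' @param path TSV path.
#' @param kind One of `"component"`, `"disease"`, `"metabolite"`. Disease
#'   files must carry `relevance_score`; metabolite files may carry a
#'   `metabolite` column naming the compound each target belongs to.
#' @return A tibble of scored targets with a `source` column.
#' @export
read_targets <- function(path, kind = c("component", "disease", "metabolite")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"symbol" %in% names(df)) {
    abort(sprintf("%s: expected a 'symbol' column", path))
  }
  if (nrow(df) == 0) {
    warn(sprintf("%s: empty target file", path))
    out <- tibble::tibble(symbol = character(), source = character())
    if (kind == "disease") out$relevance_score <- numeric()
    return(out)
  }
  bad <- which(is.na(df$symbol) | trimws(df$symbol) == "")
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed symbol at line(s) %s",
                  path, paste(bad + 1L, collapse = ", ")))
  }
  df$symbol <- canonicalize_symbols(df$symbol)
  if (kind == "disease") {
    if (!"relevance_score" %in% names(df)) {
      abort(sprintf("%s: disease targets need a 'relevance_score' column", path))
    }
    df <- df |>
      dplyr::group_by(.data$symbol) |>
      dplyr::summarise(relevance_score = max(.data$relevance_score), .groups = "drop")
  } else if (kind == "metabolite" && "metabolite" %in% names(df)) {
    df <- dplyr::distinct(df, .data$symbol, .data$metabolite)
  } else {
    df <- dplyr::distinct(df, .data$symbol)
  }
  df$source <- kind
  dplyr::arrange(df, .data$symbol)
}

#' Read a PPI edge list
#'
#' @param path TSV with columns `from`, `to`, `score` (confidence in 0-1).
#' @return A tibble of scored undirected edges.
#' @export
read_ppi_edges <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("from", "to", "score") %in% names(df)))
  df$from <- canonicalize_symbols(df$from)
  df$to <- canonicalize_symbols(df$to)
  df
}

#' Read a gene-set collection from GMT
#'
#' Tab-separated GMT: term id, description, then member symbols. Members are
#' canonicalized; empty terms are dropped with a warning.
#'
#' @param path GMT path.
#' @param background Optional character vector overriding the background
#'   universe (default: union of all members).
#' @return A `gene_set_collection`: list with `sets` (named list of symbol
#'   vectors), `descriptions`, and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    sets <- fgsea::gmtPathways(path)
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    descriptions <- setNames(
      vapply(lines, function(f) f[2], character(1)),
      vapply(lines, function(f) f[1], character(1))
    )[names(sets)]
  } else {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    sets <- setNames(
      lapply(lines, function(f) f[-(1:2)]),
      vapply(lines, function(f) f[1], character(1))
    )
    descriptions <- setNames(
      vapply(lines, function(f) f[2], character(1)), names(sets)
    )
  }
  sets <- lapply(sets, function(m) unique(canonicalize_symbols(m[m != ""])))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d empty gene set(s)", sum(empty)))
    sets <- sets[!empty]
    descriptions <- descriptions[!empty]
  }
  gene_set_collection(sets, descriptions, background)
}

#' Build a gene-set collection in memory
#'
#' @param sets Named list of member-symbol character vectors.
#' @param descriptions Optional named character vector of term descriptions.
#' @param background Optional symbol universe; defaults to the union of all
#'   members. Members outside the background are dropped with a warning.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, canonicalize_symbols)
  if (is.null(background)) {
    background <- sort(unique(unlist(sets)))
  } else {
    background <- sort(unique(canonicalize_symbols(background)))
    outside <- setdiff(unlist(sets), background)
    if (length(outside) > 0) {
      warn(sprintf("%d member symbol(s) outside background dropped", length(outside)))
      sets <- lapply(sets, intersect, background)
      keep <- lengths(sets) > 0
      sets <- sets[keep]
      if (!is.null(descriptions)) descriptions <- descriptions[names(sets)]
    }
  }
  if (is.null(descriptions)) {
    descriptions <- setNames(names(sets), names(sets))
  }
  structure(
    list(sets = sets, descriptions = descriptions, background = background),
    class = "gene_set_collection"
  )
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection` or named list of symbol vectors.
#' @param path Output GMT path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    desc <- collection$descriptions
  } else {
    sets <- collection
    desc <- setNames(names(sets), names(sets))
  }
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with columns `gene`, `sample`, `ct` and optionally `replicate` and
#' `group`; a separate sample->group map may be supplied instead.
#'
#' @param path Ct TSV path.
#' @param sample_groups Optional tibble (`sample`, `group`) when the Ct file
#'   has no `group` column.
#' @param reference_gene Name of the normalization gene (must be measured in
#'   every sample).
#' @return A `ct_table`: tibble of per-(gene, sample) Ct values (technical
#'   replicates averaged) with attributes `reference_gene`.
#' @export
read_ct_table <- function(path, sample_groups = NULL, reference_gene = "ACTB") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ct_table(df, sample_groups = sample_groups, reference_gene = reference_gene)
}

#' Write a pipeline manifest
#'
#' Records the generating configuration and planted truth next to the
#' emitted input files, as JSON.
#'
#' @param manifest A named list (config, truth, file paths).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
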