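#' Feature-intensity table
#'
#' The central container of the preprocessing pipeline: a features x samples
#' intensity matrix with per-feature metadata (m/z, retention time) and
#' per-sample metadata (group label). Group labels come from the closed
#' vocabulary N (normal), D (disease model), P (positive/reference drug),
#' H (treatment), L (low-dose treatment) and QC (pooled quality control);
#' not every dataset carries all of them.
#'
#' Every processing step returns a new `feature_table` and appends a row to
#' its processing log, so the filtering funnel is auditable after the fact.
#'
#' @param intensities Numeric matrix, features in rows, samples in columns.
#'   Missing (below detection) values are `NA`. Row and column names are
#'   taken from `feature_meta$feature_id` / `sample_meta$sample_id`.
#' @param feature_meta Data frame with columns `feature_id`, `mz`, `rt`.
#' @param sample_meta Data frame with columns `sample_id`, `group`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, feature_meta, sample_meta) {
  feature_meta <- tibble::as_tibble(feature_meta)
  sample_meta <- tibble::as_tibble(sample_meta)
  stopifnot(
    all(c("feature_id", "mz", "rt") %in% names(feature_meta)),
    all(c("sample_id", "group") %in% names(sample_meta))
  )
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != nrow(feature_meta)) {
    abort("intensity rows must match feature_meta rows")
  }
  if (ncol(intensities) != nrow(sample_meta)) {
    abort("intensity columns must match sample_meta rows")
  }
  bad_group <- setdiff(unique(sample_meta$group), c("N", "D", "P", "H", "L", "QC"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad_group, collapse = ", ")))
  }
  if (any(feature_meta$rt < 0, na.rm = TRUE)) abort("RT must be >= 0")
  if (any(feature_meta$mz <= 0, na.rm = TRUE)) abort("m/z must be > 0")
  if (any(intensities < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  rownames(intensities) <- feature_meta$feature_id
  colnames(intensities) <- sample_meta$sample_id
  structure(
    list(
      intensities = intensities,
      feature_meta = feature_meta,
      sample_meta = sample_meta,
      log = tibble::tibble(
        step = character(), features_before = integer(),
        features_after = integer(), parameters = character()
      )
    ),
    class = "feature_table"
  )
}

log_step <- function(table, step, before, after, parameters = "") {
  entry <- tibble::tibble(
    step = step, features_before = as.integer(before),
    features_after = as.integer(after), parameters = parameters
  )
  table$log <- dplyr::bind_rows(table$log, entry)
  table
}

#' @export
print.feature_table <- function(x, ...) {
  groups <- table(x$sample_meta$group)
  cat(sprintf(
    "<feature_table> %d features x %d samples (%s)\n",
    nrow(x$intensities), ncol(x$intensities),
    paste(sprintf("%s:%d", names(groups), groups), collapse = ", ")
  ))
  if (nrow(x$log) > 0) {
    cat("processing log:\n")
    print(as.data.frame(x$log), row.names = FALSE)
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Long-format view of a feature table
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) cell: `feature_id`,
#'   `mz`, `rt`, `sample_id`, `group`, `intensity` (`NA` when undetected).
#' @export
tidy.feature_table <- function(x, ...) {
  long <- tibble::as_tibble(x$intensities, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "intensity")
  long |>
    dplyr::left_join(x$feature_meta, by = "feature_id") |>
    dplyr::left_join(x$sample_meta, by = "sample_id") |>
    dplyr::select("feature_id", "mz", "rt", "sample_id", "group", "intensity")
}

#' Processing log of a feature table
#'
#' @param table A [feature_table()].
#' @return A tibble of processing steps with feature counts before/after.
#' @export
processing_log <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  table$log
}

#' Per-feature group means on the raw intensity scale
#'
#' @param table A [feature_table()].
#' @param groups Optional character vector restricting the groups.
#' @param na_rm Ignore missing cells when averaging (default `TRUE`).
#' @return A tibble `feature_id`, `group`, `mean_intensity`.
#' @export
group_means <- function(table, groups = NULL, na_rm = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  keep <- if (is.null(groups)) rep(TRUE, nrow(table$sample_meta)) else
    table$sample_meta$group %in% groups
  grp <- table$sample_meta$group[keep]
  x <- table$intensities[, keep, drop = FALSE]
  purrr::map_dfr(unique(grp), function(g) {
    tibble::tibble(
      feature_id = rownames(x),
      group = g,
      mean_intensity = unname(rowMeans(x[, grp == g, drop = FALSE], na.rm = na_rm))
    )
  })
}

subset_features <- function(table, keep) {
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$feature_meta <- table$feature_meta[keep, , drop = FALSE]
  table
}

#' Subset a feature table to chosen sample groups
#'
#' @param table A [feature_table()].
#' @param groups Character vector of group labels to keep.
#' @return A `feature_table` with only the requested samples.
#' @export
subset_groups <- function(table, groups) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$sample_meta$group %in% groups
  if (!any(keep)) abort("no samples left after group subset")
  table$intensities <- table$intensities[, keep, drop = FALSE]
  table$sample_meta <- table$sample_meta[keep, , drop = FALSE]
  table
}
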