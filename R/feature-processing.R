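# Peak-table cleaning: RT window, detection-rate filter, half-minimum
# imputation, log10 transform and scaling. Each step logs feature counts so
# the funnel is auditable; filters are per-feature predicates and therefore
# commute.

#' Retention-time window filter
#'
#' Keeps features with `rt_min <= RT <= rt_max` (inclusive endpoints:
#' excluding "less than 2 min or more than 20 min" retains values equal to
#' the endpoints). Early/late eluters are chromatographic interference under
#' the binary elution gradient.
#'
#' @param table A [feature_table()].
#' @param rt_min,rt_max Window in minutes.
#' @return Filtered `feature_table`.
#' @export
filter_by_rt <- function(table, rt_min = 2, rt_max = 20) {
  stopifnot(inherits(table, "feature_table"), rt_min < rt_max)
  keep <- table$feature_meta$rt >= rt_min & table$feature_meta$rt <= rt_max
  if (!any(keep)) warn("RT filter removed every feature")
  out <- subset_features(table, keep)
  log_step(out, "filter_by_rt", length(keep), sum(keep),
           sprintf("rt_min=%g, rt_max=%g", rt_min, rt_max))
}

#' Detection-rate filter
#'
#' A feature's detection rate in a group is its fraction of non-missing
#' values there. Under the default permissive reading a feature is kept when
#' at least one non-QC group detects it at `>= min_rate` (dropped only when
#' below the threshold in every group); `per_group = TRUE` switches to the
#' strict reading that drops a feature failing the threshold in any single
#' group.
#'
#' @param table A [feature_table()].
#' @param min_rate Minimum detection rate (fraction).
#' @param per_group Use the strict all-groups reading (default `FALSE`).
#' @return Filtered `feature_table`.
#' @export
filter_by_detection <- function(table, min_rate = 0.5, per_group = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  groups <- setdiff(unique(table$sample_meta$group), "QC")
  if (length(groups) == 0) abort("no non-QC group present")
  rates <- vapply(groups, function(g) {
    cols <- table$sample_meta$group == g
    rowMeans(!is.na(table$intensities[, cols, drop = FALSE]))
  }, numeric(nrow(table$intensities)))
  rates <- matrix(rates, nrow = nrow(table$intensities))
  keep <- if (per_group) {
    apply(rates >= min_rate, 1, all)
  } else {
    apply(rates >= min_rate, 1, any)
  }
  out <- subset_features(table, keep)
  log_step(out, "filter_by_detection", length(keep), sum(keep),
           sprintf("min_rate=%g, per_group=%s", min_rate, per_group))
}

#' Half-minimum imputation
#'
#' Replaces each missing cell by half the minimum observed intensity of that
#' feature (per-feature, across all samples) — the standard stand-in for
#' left-censored below-detection values. Observed values are untouched;
#' applying the step twice equals applying it once.
#'
#' @param table A [feature_table()].
#' @return Imputed `feature_table`.
#' @export
impute_half_minimum <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    abort(sprintf(
      "feature(s) with no observed value (should have been filtered): %s",
      paste(rownames(x)[all_missing], collapse = ", ")
    ))
  }
  mins <- apply(x, 1, min, na.rm = TRUE)
  miss <- which(is.na(x), arr.ind = TRUE)
  if (nrow(miss) > 0) x[miss] <- 0.5 * mins[miss[, 1]]
  table$intensities <- x
  log_step(table, "impute_half_minimum", nrow(x), nrow(x),
           sprintf("cells_imputed=%d", nrow(miss)))
}

#' Common (base-10) logarithmic transform
#'
#' @param table A [feature_table()] with strictly positive intensities
#'   (impute first).
#' @return Transformed `feature_table`.
#' @export
log10_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-positive intensity at feature %s, sample %s",
      rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]
    ))
  }
  table$intensities <- log10(x)
  log_step(table, "log10_transform", nrow(x), nrow(x), "")
}

#' Per-feature scaling
#'
#' Centers every feature; `"uv"` (unit variance) additionally divides by the
#' feature standard deviation and `"pareto"` by its square root. Zero-variance
#' features pass through centered with a warning. The scaling parameters are
#' attached so held-out samples can be scaled identically during
#' cross-validation (see [apply_scaling()]).
#'
#' @param table A [feature_table()] (>= 2 samples).
#' @param method `"pareto"` (default, the mass-spectrometry convention:
#'   keeps effect-size information while taming intense features), `"uv"`
#'   or `"center"`.
#' @return Scaled `feature_table` with attribute `scaling` (tibble
#'   `feature_id`, `center`, `scale`).
#' @export
scale_features <- function(table, method = c("pareto", "uv", "center")) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"), ncol(table$intensities) >= 2)
  x <- table$intensities
  ctr <- rowMeans(x)
  s <- apply(x, 1, sd)
  if (any(s == 0) && method != "center") {
    warn(sprintf("%d zero-variance feature(s) centered only", sum(s == 0)))
  }
  scl <- switch(method,
    center = rep(1, length(s)),
    uv = ifelse(s == 0, 1, s),
    pareto = ifelse(s == 0, 1, sqrt(s))
  )
  table$intensities <- (x - ctr) / scl
  params <- tibble::tibble(
    feature_id = rownames(x), center = ctr, scale = scl, method = method
  )
  attr(table, "scaling") <- params
  log_step(table, "scale_features", nrow(x), nrow(x), sprintf("method=%s", method))
}

#' Apply stored scaling parameters to a matrix
#'
#' @param x Samples x features numeric matrix (columns in the parameter
#'   order).
#' @param params Scaling tibble from [scale_features()] or the internal
#'   cross-validation fitter.
#' @return Scaled matrix.
#' @export
apply_scaling <- function(x, params) {
  sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
}

#' Full preprocessing chain
#'
#' `filter_by_rt() |> filter_by_detection() |> impute_half_minimum()`,
#' optionally followed by [log10_transform()] and [scale_features()].
#'
#' @param table A raw [feature_table()].
#' @param rt_min,rt_max RT window (minutes).
#' @param min_rate Detection-rate threshold.
#' @param log10 Apply the log10 transform.
#' @param scaling Scaling method or `NULL` to skip.
#' @return Processed `feature_table`.
#' @export
preprocess_features <- function(table, rt_min = 2, rt_max = 20, min_rate = 0.5,
                                log10 = TRUE, scaling = "pareto") {
  out <- table |>
    filter_by_rt(rt_min = rt_min, rt_max = rt_max) |>
    filter_by_detection(min_rate = min_rate) |>
    impute_half_minimum()
  if (log10) out <- log10_transform(out)
  if (!is.null(scaling)) out <- scale_features(out, method = scaling)
  out
}
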