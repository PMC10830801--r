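# The discriminant-metabolite screening cascade: VIP threshold ->
# between-group Mann-Whitney significance -> recovery trend under treatment
# -> BH-FDR over the survivors, with fold change and direction reporting.
# Fold change and recovery are computed on raw (pre-log) intensities; the
# rank-based U-test is unaffected by the log transform.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midranks for ties. In `"auto"` mode the
#' exact null distribution is used when `n_x + n_y <= 16` and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"` (default), `"exact"`, or `"asymptotic"`.
#' @return List with `u` (the U statistic for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("empty sample")
  if (length(unique(c(x, y))) == 1) {
    # degenerate: every observation tied; the test carries no information
    return(list(u = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (length(x) + length(y)) <= 16 && !ties,
    exact = TRUE,
    asymptotic = FALSE
  )
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(u = unname(ht$statistic), p = min(ht$p.value, 1))
}

#' Fold change of raw intensities
#'
#' Ratio of the arithmetic mean raw intensity in the disease group to the
#' normal group.
#'
#' @param values_d,values_n Raw (pre-log) intensity vectors.
#' @return The ratio `mean(values_d) / mean(values_n)`.
#' @export
fold_change <- function(values_d, values_n) {
  mn <- mean(values_n, na.rm = TRUE)
  if (!is.finite(mn) || mn <= 0) abort("normal-group mean must be positive")
  mean(values_d, na.rm = TRUE) / mn
}

#' Recovery flag and direction of change
#'
#' A metabolite "recovers" when the treated-group mean moves from the
#' diseased level back toward the normal level:
#' `sign(mean_H - mean_D) == sign(mean_N - mean_D)` with `mean_H != mean_D`.
#' Direction is `"U"` (up after treatment) when `mean_H > mean_D`, else
#' `"D"`.
#'
#' @param mean_n,mean_d,mean_h Group means on the raw intensity scale.
#' @param min_restoration Optional minimum restored fraction of the D-vs-N
#'   shift (`0` disables, the default: recovery is a pure sign criterion).
#' @return List with `recovery` (`"Y"`/`"N"`) and `direction` (`"U"`/`"D"`).
#' @export
recovery_flag <- function(mean_n, mean_d, mean_h, min_restoration = 0) {
  direction <- if (mean_h > mean_d) "U" else "D"
  rec <- sign(mean_h - mean_d) == sign(mean_n - mean_d) && mean_h != mean_d
  if (rec && min_restoration > 0) {
    rec <- abs(mean_h - mean_d) >= min_restoration * abs(mean_n - mean_d)
  }
  list(recovery = if (rec) "Y" else "N", direction = direction)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (elementwise `>=` the raw values).
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Discriminant-metabolite screening cascade
#'
#' Ordered stages over a preprocessed (imputed, raw-scale) feature table:
#' \enumerate{
#'   \item VIP greater than `vip_min`;
#'   \item two-sided Mann-Whitney raw p below `p_max` between groups N and D;
#'   \item recovery of the treated group (H) toward normal;
#'   \item BH-FDR computed over exactly the stage-3 survivors, keep adjusted
#'     p below `fdr_max` (set `fdr_scope = "all"` to adjust over every
#'     feature instead).
#' }
#' All thresholds are strict inequalities. Every feature's record keeps the
#' last stage it passed, so the funnel is auditable.
#'
#' @param table A [feature_table()] on the raw intensity scale with groups
#'   N, D and H present (imputed; remaining `NA`s are ignored in means).
#' @param vip_scores Tibble `feature_id`, `vip` (from [vip()]), aligned to
#'   the table's features.
#' @param vip_min,p_max,fdr_max Cascade thresholds.
#' @param fdr_scope `"survivors"` (default: FDR family = stage-3 survivors)
#'   or `"all"` (whole-table adjustment).
#' @param min_restoration Passed to [recovery_flag()].
#' @return A `screen_records` tibble: per feature VIP, raw p, fold change,
#'   recovery, direction, adjusted p (survivor scope: `NA` outside the FDR
#'   family), `passed_stage` (0-4) and `selected`.
#' @export
screen_cascade <- function(table, vip_scores, vip_min = 1.5, p_max = 0.05,
                           fdr_max = 0.05, fdr_scope = c("survivors", "all"),
                           min_restoration = 0) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(table, "feature_table"))
  need <- c("N", "D", "H")
  missing_grp <- setdiff(need, unique(table$sample_meta$group))
  if (length(missing_grp) > 0) {
    abort(paste0("missing group(s): ", paste(missing_grp, collapse = ", ")))
  }
  ids <- table$feature_meta$feature_id
  vip_scores <- tibble::as_tibble(vip_scores)
  if (!all(ids %in% vip_scores$feature_id)) {
    abort("vip_scores must cover every feature in the table")
  }
  v <- vip_scores$vip[match(ids, vip_scores$feature_id)]
  grp <- table$sample_meta$group
  xn <- table$intensities[, grp == "N", drop = FALSE]
  xd <- table$intensities[, grp == "D", drop = FALSE]
  xh <- table$intensities[, grp == "H", drop = FALSE]

  rec <- purrr::map_dfr(seq_along(ids), function(i) {
    mw <- mann_whitney_u(xn[i, ], xd[i, ])
    mn <- mean(xn[i, ], na.rm = TRUE)
    md <- mean(xd[i, ], na.rm = TRUE)
    mh <- mean(xh[i, ], na.rm = TRUE)
    rf <- recovery_flag(mn, md, mh, min_restoration = min_restoration)
    tibble::tibble(
      feature_id = ids[i], vip = v[i], raw_p = mw$p,
      fold_change = md / mn,
      recovery = rf$recovery, direction = rf$direction
    )
  })

  s1 <- rec$vip > vip_min
  s2 <- s1 & rec$raw_p < p_max
  s3 <- s2 & rec$recovery == "Y"
  rec$adjusted_p <- NA_real_
  if (fdr_scope == "survivors") {
    if (any(s3)) rec$adjusted_p[s3] <- bh_fdr(rec$raw_p[s3])
  } else {
    rec$adjusted_p <- bh_fdr(rec$raw_p)
  }
  s4 <- s3 & !is.na(rec$adjusted_p) & rec$adjusted_p < fdr_max
  rec$passed_stage <- 0L + s1 + s2 + s3 + s4
  rec$selected <- s4
  rec <- dplyr::arrange(rec, dplyr::desc(.data$selected), .data$raw_p,
                        dplyr::desc(.data$vip))
  attr(rec, "thresholds") <- list(
    vip_min = vip_min, p_max = p_max, fdr_max = fdr_max,
    fdr_scope = fdr_scope, fdr_family_size = sum(s3)
  )
  attr(rec, "log") <- tibble::tibble(
    step = c("vip", "u_test", "recovery", "fdr"),
    features_before = c(length(s1), sum(s1), sum(s2), sum(s3)),
    features_after = c(sum(s1), sum(s2), sum(s3), sum(s4)),
    parameters = c(
      sprintf("vip>%g", vip_min), sprintf("raw_p<%g", p_max),
      "recovery=Y", sprintf("adjusted_p<%g (family=%d)", fdr_max, sum(s3))
    )
  )
  class(rec) <- c("screen_records", class(rec))
  rec
}

#' Screened metabolites with annotation context
#'
#' Joins screening records to annotation hits so selected features carry
#' compound names, classes and formulas, mirroring a published
#' target-metabolite table.
#'
#' @param records A `screen_records` tibble from [screen_cascade()].
#' @param hits Annotation hits from [match_features()] /
#'   [annotate_features()] (best hit per feature is used).
#' @param table Optional [feature_table()] supplying m/z and RT metadata.
#' @return Tibble of selected features with annotation columns.
#' @export
screen_report <- function(records, hits = NULL, table = NULL) {
  out <- dplyr::filter(tibble::as_tibble(records), .data$selected)
  if (!is.null(table)) {
    out <- dplyr::left_join(out, table$feature_meta, by = "feature_id")
  }
  if (!is.null(hits) && nrow(hits) > 0) {
    best <- hits |>
      dplyr::group_by(.data$feature_id) |>
      dplyr::slice_min(abs(.data$error_ppm), n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("feature_id", "compound_id", "name", "class",
                    "theoretical_mz", "error_ppm")
    out <- dplyr::left_join(out, best, by = "feature_id")
  }
  out
}
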