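# 2^-ddCt relative-expression analysis: per-sample delta-Ct against a
# reference gene, delta-delta-Ct against the arithmetic-mean delta-Ct of the
# calibrator group, group comparison by Mann-Whitney U, and the retracement
# check for the treated group. Amplification efficiency is fixed at 2.

#' Construct a qPCR Ct table
#'
#' Technical replicates (rows sharing gene and sample) are averaged before
#' analysis.
#'
#' @param df Data frame with columns `gene`, `sample`, `ct` and either a
#'   `group` column or a `sample_groups` map.
#' @param sample_groups Optional tibble (`sample`, `group`).
#' @param reference_gene Normalization gene; must be measured in every
#'   sample and have Ct > 0 everywhere.
#' @return A `ct_table` tibble (`gene`, `sample`, `group`, `ct`) with
#'   attribute `reference_gene`.
#' @export
ct_table <- function(df, sample_groups = NULL, reference_gene = "ACTB") {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("gene", "sample", "ct") %in% names(df)))
  if (!"group" %in% names(df)) {
    if (is.null(sample_groups)) abort("need a 'group' column or sample_groups")
    df <- dplyr::left_join(df, sample_groups, by = "sample")
  }
  df <- df |>
    dplyr::group_by(.data$gene, .data$sample, .data$group) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  if (any(df$ct <= 0, na.rm = TRUE)) abort("Ct values must be positive")
  samples <- unique(df$sample)
  ref_samples <- df$sample[df$gene == reference_gene]
  if (!all(samples %in% ref_samples)) {
    abort(sprintf("reference gene '%s' missing in some samples", reference_gene))
  }
  attr(df, "reference_gene") <- reference_gene
  class(df) <- c("ct_table", class(df))
  df
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample: `dCt = Ct_target - Ct_reference`;
#' `ddCt = dCt - mean(dCt of the calibrator group, same gene)`;
#' `RQ = 2^-ddCt`. The calibrator group's mean ddCt is 0 by construction,
#' so its geometric-mean RQ is exactly 1 for every gene.
#'
#' @param ct A [ct_table()].
#' @param reference_gene Overrides the table's reference gene.
#' @param calibrator_group Calibrator (baseline) group label.
#' @return A `relative_expression` object: `samples` tibble (per gene and
#'   sample `d_ct`, `dd_ct`, `rq`) and `groups` tibble (per gene and group
#'   mean/SD of RQ), with attributes.
#' @export
delta_delta_ct <- function(ct, reference_gene = NULL, calibrator_group = "N") {
  stopifnot(inherits(ct, "ct_table"))
  reference_gene <- reference_gene %||% attr(ct, "reference_gene")
  if (!calibrator_group %in% ct$group) abort("calibrator group absent")
  ref <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample", ref_ct = "ct")
  d <- ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::inner_join(ref, by = "sample") |>
    dplyr::mutate(d_ct = .data$ct - .data$ref_ct)
  dropped <- dplyr::anti_join(
    dplyr::filter(ct, .data$gene != reference_gene), d,
    by = c("gene", "sample")
  )
  if (nrow(dropped) > 0) {
    warn(sprintf("%d (gene, sample) cell(s) without reference Ct skipped",
                 nrow(dropped)))
  }
  cal <- d |>
    dplyr::filter(.data$group == calibrator_group) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(cal_mean = mean(.data$d_ct), .groups = "drop")
  samples <- d |>
    dplyr::inner_join(cal, by = "gene") |>
    dplyr::mutate(dd_ct = .data$d_ct - .data$cal_mean, rq = 2^(-.data$dd_ct)) |>
    dplyr::select("gene", "sample", "group", "d_ct", "dd_ct", "rq")
  groups <- samples |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(
      mean_rq = mean(.data$rq), sd_rq = sd(.data$rq), n = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(samples = samples, groups = groups),
    reference_gene = reference_gene, calibrator_group = calibrator_group,
    class = "relative_expression"
  )
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf(
    "<relative_expression> %d gene(s), calibrator %s, reference %s\n",
    length(unique(x$samples$gene)), attr(x, "calibrator_group"),
    attr(x, "reference_gene")
  ))
  print(x$groups)
  invisible(x)
}

#' Per-sample relative-expression values
#'
#' @param x A `relative_expression`.
#' @param ... Unused.
#' @return Tibble of per-(gene, sample) `d_ct`, `dd_ct`, `rq`.
#' @export
tidy.relative_expression <- function(x, ...) x$samples

#' Per-group relative-expression summary
#'
#' @param x A `relative_expression`.
#' @param ... Unused.
#' @return Tibble of per-(gene, group) mean and SD of RQ.
#' @export
glance.relative_expression <- function(x, ...) x$groups

significance_mark <- function(p) {
  dplyr::case_when(p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "")
}

#' Compare relative expression between two groups
#'
#' Two-sided Mann-Whitney U on per-sample RQ values, with the conventional
#' significance marks (* p < 0.05, ** p < 0.01).
#'
#' @param re A `relative_expression`.
#' @param gene Gene symbol, or `NULL` for all genes.
#' @param groups Length-2 character vector of group labels.
#' @return Tibble `gene`, `group_1`, `group_2`, `u`, `p_value`, `mark`.
#' @export
expression_compare <- function(re, gene = NULL, groups = c("N", "D")) {
  stopifnot(inherits(re, "relative_expression"), length(groups) == 2)
  genes <- gene %||% unique(re$samples$gene)
  purrr::map_dfr(genes, function(g) {
    x <- re$samples$rq[re$samples$gene == g & re$samples$group == groups[1]]
    y <- re$samples$rq[re$samples$gene == g & re$samples$group == groups[2]]
    if (length(x) < 2 || length(y) < 2) abort("need >= 2 samples per group")
    mw <- mann_whitney_u(x, y)
    tibble::tibble(
      gene = g, group_1 = groups[1], group_2 = groups[2],
      u = mw$u, p_value = mw$p, mark = significance_mark(mw$p)
    )
  })
}

#' Retracement check for a treated group
#'
#' Flags a gene when its treated-group mean RQ moved from the diseased
#' level back toward the normal level *and* the disease-vs-treated
#' comparison is significant (p < `p_max`) — "significant retracement".
#'
#' @param re A `relative_expression` with groups N, D and H present.
#' @param gene Gene symbol, or `NULL` for all genes.
#' @param p_max Significance threshold for the D-vs-H comparison.
#' @return Tibble `gene`, `mean_rq_n/d/h`, `p_dh`, `retracement`.
#' @export
retracement_check <- function(re, gene = NULL, p_max = 0.05) {
  stopifnot(inherits(re, "relative_expression"))
  need <- c("N", "D", "H")
  if (!all(need %in% re$samples$group)) abort("groups N, D, H required")
  genes <- gene %||% unique(re$samples$gene)
  purrr::map_dfr(genes, function(g) {
    m <- re$groups[re$groups$gene == g, ]
    mn <- m$mean_rq[m$group == "N"]
    md <- m$mean_rq[m$group == "D"]
    mh <- m$mean_rq[m$group == "H"]
    p_dh <- expression_compare(re, g, c("D", "H"))$p_value
    back <- sign(mh - md) == sign(mn - md) && mh != md
    tibble::tibble(
      gene = g, mean_rq_n = mn, mean_rq_d = md, mean_rq_h = mh,
      p_dh = p_dh, retracement = back && p_dh < p_max
    )
  })
}
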