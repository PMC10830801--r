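# ggplot2 views of the main result types.

#' Score plot of an OPLS-DA model
#'
#' First predictive score against the second predictive (or first
#' orthogonal) score, colored by group.
#'
#' @param object An `opls_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.opls_model <- function(object, ...) {
  sc <- opls_scores(object)
  yvar <- if ("t2" %in% names(sc)) "t2" else if ("to1" %in% names(sc)) "to1" else "t1"
  ggplot2::ggplot(sc, ggplot2::aes(.data$t1, .data[[yvar]], colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "predictive score t1", y = paste("score", yvar),
      title = sprintf("OPLS-DA scores (R2Y %.3f, Q2 %.3f)", object$r2y, object$q2)
    ) +
    ggplot2::theme_minimal()
}

#' Permutation-test plot
#'
#' Permuted R2Y and Q2 against the label correlation, with the regression
#' lines whose intercepts estimate chance-level fit; the unpermuted model
#' sits at correlation 1.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.permutation_result <- function(object, ...) {
  pts <- dplyr::bind_rows(
    dplyr::mutate(object$permutations, kind = "permuted"),
    tibble::tibble(perm = NA, r = 1, r2y = object$real_r2y,
                   q2 = object$real_q2, kind = "real")
  ) |>
    tidyr::pivot_longer(c("r2y", "q2"), names_to = "metric")
  ggplot2::ggplot(pts, ggplot2::aes(.data$r, .data$value, colour = .data$metric)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$kind), alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, fullrange = TRUE) +
    ggplot2::labs(
      x = "|correlation with original labels|", y = "R2Y / Q2",
      title = sprintf("Permutation test (intercepts R2 %.3f, Q2 %.3f)",
                      object$r2_intercept, object$q2_intercept)
    ) +
    ggplot2::theme_minimal()
}

#' PCA score plot of a feature table
#'
#' @param table A processed (scaled) [feature_table()].
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 colored by group (QC included).
#' @export
plot_pca <- function(table, ...) {
  sc <- pca_scores(table, k = 2)
  ev <- attr(sc, "explained")
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    ) +
    ggplot2::theme_minimal()
}

#' VIP / fold-change screening plot
#'
#' Each feature's VIP against its log2 fold change, with the cascade
#' thresholds drawn; selected features highlighted.
#'
#' @param records A `screen_records` tibble from [screen_cascade()].
#' @param vip_min VIP threshold line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_screen <- function(records, vip_min = 1.5, ...) {
  df <- tibble::as_tibble(records)
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$fold_change), .data$vip,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = vip_min, linetype = 2) +
    ggplot2::labs(x = "log2 fold change (D vs N)", y = "VIP") +
    ggplot2::theme_minimal()
}

#' Relative-expression bar plot
#'
#' Group mean RQ with SD error bars per gene.
#'
#' @param object A `relative_expression`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.relative_expression <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(.data$group, .data$mean_rq, fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rq - .data$sd_rq,
                   ymax = .data$mean_rq + .data$sd_rq),
      width = 0.3
    ) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(y = "relative expression (2^-ddCt)") +
    ggplot2::theme_minimal()
}
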