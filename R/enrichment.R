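# Local over-representation analysis: one-sided hypergeometric tail with
# BH adjustment over the tested terms, standing in for web-service GO/KEGG
# enrichment so the workflow runs offline.

#' Hypergeometric over-representation analysis
#'
#' For each term with overlap `k >= min_overlap`:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with background size
#' `N`, term size `K` and query size `n`; BH adjustment across tested
#' terms; `fold_enrichment = (k / n) / (K / N)`.
#'
#' @param query Character vector of gene symbols. Symbols outside the
#'   background are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param min_overlap Minimum overlap for a term to be tested.
#' @return Tibble per tested term: `term`, `description`, `overlap`,
#'   `term_size`, `query_size`, `background_size`, `fold_enrichment`,
#'   `p_value`, `q_value`, `genes` (comma-separated overlap), sorted by
#'   p-value.
#' @export
hypergeometric_ora <- function(query, collection, min_overlap = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  bg <- collection$background
  if (length(bg) == 0) abort("empty background")
  query <- unique(canonicalize_symbols(query))
  outside <- setdiff(query, bg)
  if (length(outside) > 0) {
    warn(sprintf("%d query symbol(s) outside background dropped", length(outside)))
    query <- intersect(query, bg)
  }
  n <- length(query)
  n_bg <- length(bg)
  res <- purrr::imap_dfr(collection$sets, function(members, term) {
    members <- intersect(members, bg)
    hit <- intersect(query, members)
    k <- length(hit)
    if (k < min_overlap) return(NULL)
    big_k <- length(members)
    tibble::tibble(
      term = term,
      description = unname(collection$descriptions[term]),
      overlap = k, term_size = big_k, query_size = n, background_size = n_bg,
      fold_enrichment = (k / n) / (big_k / n_bg),
      p_value = phyper(k - 1, big_k, n_bg - big_k, n, lower.tail = FALSE),
      genes = paste(sort(hit), collapse = ",")
    )
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(
      term = character(), description = character(), overlap = integer(),
      term_size = integer(), query_size = integer(),
      background_size = integer(), fold_enrichment = numeric(),
      p_value = numeric(), q_value = numeric(), genes = character()
    ))
  }
  res$q_value <- bh_fdr(res$p_value)
  dplyr::arrange(res, .data$p_value, .data$term) |>
    dplyr::relocate("q_value", .after = "p_value")
}
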