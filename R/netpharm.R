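# Target-set assembly, PPI centrality screening and the three-way
# integration of component, disease and metabolite target sets. Centrality
# conventions follow the NetworkAnalyzer normalizations (betweenness scaled
# by 2/((N-1)(N-2)); closeness = 1 / average shortest-path distance to
# reachable nodes), computed per connected component, because the published
# screening thresholds are only meaningful on normalized scales.

#' Filter disease targets by relevance score
#'
#' @param targets Tibble with `symbol` and `relevance_score` (see
#'   [read_targets()]).
#' @param min_score Strict threshold: keep `relevance_score > min_score`.
#' @return Filtered tibble.
#' @export
filter_disease_targets <- function(targets, min_score = 20) {
  stopifnot("relevance_score" %in% names(targets))
  dplyr::filter(targets, .data$relevance_score > min_score)
}

#' Intersect target sets
#'
#' @param ... Two or more character vectors (or tibbles with a `symbol`
#'   column) of canonicalized gene symbols.
#' @return Sorted character vector of common symbols.
#' @export
intersect_targets <- function(...) {
  sets <- lapply(list(...), function(s) {
    if (is.data.frame(s)) s <- s$symbol
    unique(canonicalize_symbols(s))
  })
  sort(Reduce(intersect, sets))
}

#' Build a PPI graph from a scored edge list
#'
#' Keeps edges whose both endpoints are in the whitelist and whose
#' confidence score is at least `min_edge_score`; duplicate edges collapse
#' to the maximum score, self-loops are dropped, and isolated whitelist
#' nodes are retained as degree-0 nodes.
#'
#' @param edges Tibble `from`, `to`, `score` (see [read_ppi_edges()]).
#' @param node_whitelist Character vector of node symbols to keep (default:
#'   every symbol in the edge list).
#' @param min_edge_score Confidence cutoff (STRING-style; 0.4 = medium).
#' @return An undirected `igraph` object with edge attribute `score`.
#' @export
build_ppi <- function(edges, node_whitelist = NULL, min_edge_score = 0.4) {
  edges <- tibble::as_tibble(edges)
  edges$from <- canonicalize_symbols(edges$from)
  edges$to <- canonicalize_symbols(edges$to)
  if (is.null(node_whitelist)) {
    node_whitelist <- unique(c(edges$from, edges$to))
  }
  node_whitelist <- sort(unique(canonicalize_symbols(node_whitelist)))
  keep <- edges$from %in% node_whitelist & edges$to %in% node_whitelist &
    edges$score >= min_edge_score & edges$from != edges$to
  edges <- edges[keep, , drop = FALSE]
  if (nrow(edges) > 0) {
    key <- purrr::map2_chr(edges$from, edges$to,
                           ~ paste(sort(c(.x, .y)), collapse = "|"))
    edges <- edges |>
      dplyr::mutate(.key = key) |>
      dplyr::group_by(.data$.key) |>
      dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-".key")
  }
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = node_whitelist)
  )
}

#' Node centralities with NetworkAnalyzer-style normalization
#'
#' Degree is the unweighted edge count. Betweenness (Brandes, unweighted
#' shortest paths) is normalized by `2 / ((N - 1) (N - 2))` and closeness is
#' `(N - 1) / sum(d)` — both with `N` the node count of the node's own
#' connected component, so disconnected graphs get plain per-component
#' values. Isolated nodes get betweenness 0 and closeness `NA`.
#'
#' @param g An undirected `igraph` (>= 2 nodes).
#' @return Tibble `node`, `degree`, `betweenness`, `closeness`, `component`.
#' @export
centralities <- function(g) {
  if (igraph::vcount(g) < 2) abort("graph needs at least 2 nodes")
  comp <- igraph::components(g)
  out <- purrr::map_dfr(seq_len(comp$no), function(ci) {
    members <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, members)
    n <- igraph::vcount(sub)
    btw <- if (n > 2) {
      igraph::betweenness(sub, directed = FALSE, weights = NA) *
        2 / ((n - 1) * (n - 2))
    } else {
      rep(0, n)
    }
    cls <- if (n > 1) {
      suppressWarnings(
        igraph::closeness(sub, weights = NA, normalized = TRUE)
      )
    } else {
      rep(NA_real_, n)
    }
    tibble::tibble(
      node = igraph::V(sub)$name,
      degree = unname(igraph::degree(sub)),
      betweenness = unname(btw),
      closeness = unname(cls),
      component = ci
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$node)
}

#' Screen critical targets by centrality thresholds
#'
#' Strict conjunction: `degree > deg_min & betweenness > bc_min &
#' closeness > cc_min`.
#'
#' @param records Centrality tibble from [centralities()].
#' @param deg_min,bc_min,cc_min Strict thresholds (defaults are the
#'   screening conditions of the workflow this package implements).
#' @return Sorted character vector of critical-target symbols.
#' @export
screen_critical_targets <- function(records, deg_min = 11, bc_min = 0.00533,
                                    cc_min = 0.5236) {
  keep <- records$degree > deg_min &
    !is.na(records$betweenness) & records$betweenness > bc_min &
    !is.na(records$closeness) & records$closeness > cc_min
  sort(records$node[keep])
}

#' Integrate critical targets with metabolite targets
#'
#' Intersects the centrality-screened critical set with the union of
#' targets of the screened metabolites, keeping per-target provenance
#' (which metabolites point at it).
#'
#' @param critical Character vector of critical-target symbols.
#' @param metabolite_targets Tibble with `symbol` and optionally
#'   `metabolite` columns (see [read_targets()]), or a character vector.
#' @return Tibble `symbol`, `metabolites` (comma-separated provenance; `NA`
#'   when no metabolite column was available), one row per final target.
#' @export
integrate_metabolite_targets <- function(critical, metabolite_targets) {
  critical <- canonicalize_symbols(critical)
  if (!is.data.frame(metabolite_targets)) {
    metabolite_targets <- tibble::tibble(
      symbol = canonicalize_symbols(metabolite_targets)
    )
  }
  metabolite_targets$symbol <- canonicalize_symbols(metabolite_targets$symbol)
  final <- sort(intersect(critical, unique(metabolite_targets$symbol)))
  prov <- if ("metabolite" %in% names(metabolite_targets)) {
    metabolite_targets |>
      dplyr::filter(.data$symbol %in% final) |>
      dplyr::group_by(.data$symbol) |>
      dplyr::summarise(
        metabolites = paste(sort(unique(.data$metabolite)), collapse = ","),
        .groups = "drop"
      )
  } else {
    tibble::tibble(symbol = final, metabolites = NA_character_)
  }
  dplyr::left_join(tibble::tibble(symbol = final), prov, by = "symbol")
}

#' Export a network
#'
#' @param g An `igraph` object.
#' @param path Output path.
#' @param format `"sif"` (lines `A interacts B`), `"graphml"` (node/edge
#'   attributes preserved; round-trips through [igraph::read_graph()]), or
#'   `"tsv"` (edge list with scores).
#' @param annotations Optional tibble `node`, ... merged onto node
#'   attributes before export.
#' @return `path`, invisibly.
#' @export
export_network <- function(g, path, format = c("sif", "graphml", "tsv"),
                           annotations = NULL) {
  format <- match.arg(format)
  if (!is.null(annotations)) {
    idx <- match(igraph::V(g)$name, annotations$node)
    for (col in setdiff(names(annotations), "node")) {
      g <- igraph::set_vertex_attr(g, col, value = annotations[[col]][idx])
    }
  }
  if (format == "sif") {
    el <- igraph::as_edgelist(g)
    writeLines(
      if (nrow(el) > 0) paste(el[, 1], "interacts", el[, 2]) else character(),
      path
    )
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    readr::write_tsv(tibble::as_tibble(el), path)
  }
  invisible(path)
}

#' Layered component-metabolite-target-pathway-disease network
#'
#' Builds the integrative visualization network: one disease node, pathway
#' (enriched-term) nodes, final target nodes, the screened metabolites that
#' point at them, and the components. Each node carries a `layer`
#' attribute.
#'
#' @param components Character vector of component names.
#' @param metabolites Character vector of screened metabolite names.
#' @param targets Final-target tibble from [integrate_metabolite_targets()].
#' @param pathways Character vector of enriched term ids.
#' @param disease Disease node name.
#' @param component_targets Optional tibble `symbol` linking components'
#'   targets (edges component -> target drawn for targets present).
#' @return An `igraph` with `layer` vertex attribute.
#' @export
layered_network <- function(components, metabolites, targets, pathways,
                            disease = "DISEASE", component_targets = NULL) {
  nodes <- tibble::tibble(
    name = c(components, metabolites, targets$symbol, pathways, disease),
    layer = c(
      rep("component", length(components)),
      rep("metabolite", length(metabolites)),
      rep("target", nrow(targets)),
      rep("pathway", length(pathways)),
      "disease"
    )
  )
  edges <- list()
  if (!is.na(targets$metabolites[1] %||% NA)) {
    edges$mt <- targets |>
      tidyr::separate_rows("metabolites", sep = ",") |>
      dplyr::filter(.data$metabolites %in% metabolites) |>
      dplyr::transmute(from = .data$metabolites, to = .data$symbol)
  }
  edges$comp <- tidyr::expand_grid(from = components, to = targets$symbol)
  edges$path <- tidyr::expand_grid(from = targets$symbol, to = pathways)
  edges$dis <- tibble::tibble(from = pathways, to = disease)
  el <- dplyr::bind_rows(edges)
  el <- dplyr::filter(el, .data$from %in% nodes$name, .data$to %in% nodes$name)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
}
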