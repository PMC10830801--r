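test_that("target reading canonicalizes, dedups, and filters strictly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    symbol = c(" akt1", "KDR", "kdr", "EGFR"),
    relevance_score = c(25, 25, 30, 20.1)
  ), path)
  targets <- read_targets(path, "disease")
  expect_equal(targets$symbol, c("AKT1", "EGFR", "KDR"))
  expect_equal(targets$relevance_score[targets$symbol == "KDR"], 30)
  kept <- filter_disease_targets(
    tibble::tibble(symbol = c("A", "B"), relevance_score = c(20.0, 20.1)), 20
  )
  expect_equal(kept$symbol, "B")
  empty <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(symbol = character()), empty)
  expect_warning(out <- read_targets(empty, "component"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("target intersection is exact and order-stable", {
  expect_equal(intersect_targets(c("AKT1", "KDR"), c("KDR", "TP53")), "KDR")
  expect_equal(intersect_targets(c("A"), c("B")), character())
  expect_equal(intersect_targets(c("b", "a", "c"), c("C", "A", "B"), c("a", "c")),
               c("A", "C"))
})

test_that("PPI construction applies score cutoff, dedup, and whitelist", {
  edges <- tibble::tibble(
    from = c("A", "A", "B", "C", "X"),
    to = c("B", "B", "C", "C", "A"),
    score = c(0.5, 0.9, 0.39, 0.8, 0.9)
  )
  g <- build_ppi(edges, node_whitelist = c("A", "B", "C", "D"),
                 min_edge_score = 0.4)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g), 1) # A-B kept (max 0.9); B-C below cutoff;
                                     # C-C self-loop dropped; X not whitelisted
  expect_equal(igraph::E(g)$score, 0.9)
  expect_equal(unname(igraph::degree(g)["D"]), 0)
})

test_that("path and complete graphs give textbook centralities", {
  path_g <- build_ppi(tibble::tibble(
    from = c("A", "B"), to = c("B", "C"), score = 1
  ))
  cent <- centralities(path_g)
  b <- cent[cent$node == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$betweenness, 1)
  expect_equal(b$closeness, 1)
  expect_equal(cent$closeness[cent$node == "A"], 2 / 3)
  k4 <- build_ppi(tibble::tibble(
    from = c("A", "A", "A", "B", "B", "C"),
    to = c("B", "C", "D", "C", "D", "D"), score = 1
  ))
  c4 <- centralities(k4)
  expect_equal(c4$betweenness, rep(0, 4))
  expect_equal(c4$closeness, rep(1, 4))
  expect_equal(sum(c4$degree), 2 * igraph::ecount(k4))
})

test_that("centralities match a BFS path-counting oracle on random graphs", {
  for (s in 1:10) {
    rg <- random_graph(n = sample(8:20, 1), p = 0.2, seed = s)
    g <- build_ppi(rg$edges, node_whitelist = rg$nodes, min_edge_score = 0)
    got <- centralities(g)
    want <- oracle_centralities(rg$edges, igraph::V(g)$name)
    got <- got[order(got$node), ]
    want <- want[order(want$node), ]
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
  }
})

test_that("critical-target screening is a strict conjunction", {
  rec <- tibble::tibble(
    node = c("PASS", "DEG", "BC", "CC"),
    degree = c(12, 11, 20, 20),
    betweenness = c(0.006, 0.9, 0.00533, 0.9),
    closeness = c(0.60, 0.9, 0.9, 0.5236),
    component = 1
  )
  expect_equal(screen_critical_targets(rec), "PASS")
  # raising any threshold never grows the set
  expect_lte(length(screen_critical_targets(rec, deg_min = 15)), 1)
  expect_equal(screen_critical_targets(rec, deg_min = 15), character())
})

test_that("metabolite integration intersects with provenance", {
  final <- integrate_metabolite_targets(
    c("AKT1", "EGFR"),
    tibble::tibble(symbol = c("AKT1", "PPARA", "AKT1"),
                   metabolite = c("SM", "LPC", "LPC"))
  )
  expect_equal(final$symbol, "AKT1")
  expect_equal(final$metabolites, "LPC,SM")
  expect_equal(nrow(integrate_metabolite_targets(c("AKT1"), character())), 0)
})

test_that("network export round-trips and SIF has one line per edge", {
  g <- build_ppi(tibble::tibble(from = c("A", "B"), to = c("B", "C"), score = 1))
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(g, sif, "sif")
  expect_equal(length(readLines(sif)), 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  cent <- centralities(g)
  export_network(g, gml, "graphml", annotations = cent)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(
    sort(igraph::V(g2)$degree),
    sort(cent$degree[match(igraph::V(g2)$name, cent$node)])
  )
})

test_that("the layered network counts one node per entity plus the disease", {
  targets <- tibble::tibble(symbol = c("T1", "T2"), metabolites = c("M1", "M1,M2"))
  g <- layered_network(
    components = c("comp1", "comp2"), metabolites = c("M1", "M2"),
    targets = targets, pathways = c("P1")
  )
  expect_equal(igraph::vcount(g), 2 + 2 + 2 + 1 + 1)
  expect_setequal(unique(igraph::V(g)$layer),
                  c("component", "metabolite", "target", "pathway", "disease"))
})
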