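test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_planted = 10, n_features = 5), "n_planted")
  expect_error(sim_config(recovery_fraction = 1.2), "recovery_fraction")
  expect_error(sim_config(n_per_group = 0), "counts")
})

test_that("identical seeds give byte-identical outputs", {
  a <- generate_feature_table(sim_config(n_features = 50, seed = 42))
  b <- generate_feature_table(sim_config(n_features = 50, seed = 42))
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$table$feature_meta, b$table$feature_meta)
  expect_identical(a$truth, b$truth)
  d1 <- generate_target_databases(seed = 9)
  d2 <- generate_target_databases(seed = 9)
  expect_identical(d1$ppi_edges, d2$ppi_edges)
  expect_identical(d1$disease_targets, d2$disease_targets)
  c1 <- generate_ct_table(c("G1", "ACTB"), seed = 4)
  c2 <- generate_ct_table(c("G1", "ACTB"), seed = 4)
  expect_identical(c1$ct, c2$ct)
})

test_that("a null configuration plants no group effect", {
  sim <- generate_feature_table(sim_config(n_planted = 0, n_features = 200,
                                           seed = 21))
  expect_length(sim$truth$differential_feature_ids, 0)
  gm <- group_means(sim$table, c("N", "D"))
  wide <- tidyr::pivot_wider(gm, names_from = "group",
                             values_from = "mean_intensity")
  # features fully censored in a group have no mean; compare the rest
  ratio <- (wide$D / wide$N)[is.finite(wide$D / wide$N)]
  expect_gt(length(ratio), 150)
  # two-group means differ only by noise: no systematic shift, modest spread
  expect_lt(abs(median(log(ratio))), 0.1)
  expect_gt(mean(abs(log(ratio)) < 0.3), 0.95)
})

test_that("planted features carry the configured fold change", {
  sim <- generate_feature_table(sim_config(seed = 1))
  gm <- group_means(sim$table, c("N", "D"))
  wide <- tidyr::pivot_wider(gm, names_from = "group",
                             values_from = "mean_intensity")
  planted <- wide[wide$feature_id %in% sim$truth$differential_feature_ids, ]
  ratios <- planted$D / planted$N
  expect_gte(sum(ratios >= 2 & ratios <= 4.5), 9)
  # treatment moves planted features back toward normal, H more than P
  gm4 <- group_means(sim$table)
  w4 <- tidyr::pivot_wider(gm4, names_from = "group",
                           values_from = "mean_intensity")
  p4 <- w4[w4$feature_id %in% sim$truth$differential_feature_ids, ]
  expect_true(all(p4$H < p4$D))
  expect_gt(mean(p4$H < p4$P), 0.7)
})

test_that("missing cells are exactly the censored low-intensity cells", {
  cfg <- sim_config(n_features = 100, seed = 33, detection_limit_quantile = 0.1)
  sim <- generate_feature_table(cfg)
  x <- sim$table$intensities
  expect_true(all(x >= sim$truth$detection_limit, na.rm = TRUE))
  # the censored fraction matches the configured quantile
  expect_equal(mean(is.na(x)), 0.1, tolerance = 0.02)
})

test_that("planted truth ids exist in the emitted artifacts", {
  sim <- generate_feature_table(sim_config(seed = 2))
  expect_true(all(sim$truth$differential_feature_ids %in%
                    sim$table$feature_meta$feature_id))
  expect_true(all(sim$truth$annotation$feature_id %in%
                    sim$truth$differential_feature_ids))
  db <- generate_target_databases(seed = 2)
  crit <- db$truth$planted_critical_targets
  expect_true(all(crit %in% db$component_targets$symbol))
  expect_true(all(crit %in% db$disease_targets$symbol))
  expect_true(all(crit %in% db$metabolite_targets$symbol))
  expect_true(all(db$disease_targets$relevance_score[
    db$disease_targets$symbol %in% crit] > 20))
})

test_that("annotated planted features match library compounds within 10 ppm", {
  sim <- generate_feature_table(sim_config(seed = 12))
  hits <- match_features(sim$table, demo_compound_library(), tol_ppm = 10)
  expect_true(all(sim$truth$annotation$feature_id %in% hits$feature_id))
  joined <- dplyr::inner_join(hits, sim$truth$annotation,
                              by = c("feature_id", "compound_id"))
  expect_equal(nrow(joined), nrow(sim$truth$annotation))
  # decoys stay clear of the library adducts
  decoy_hits <- setdiff(hits$feature_id, sim$truth$annotation$feature_id)
  expect_length(decoy_hits, 0)
})

test_that("three-way target intersection equals the planted overlap exactly", {
  db <- generate_target_databases(n_planted_critical = 6, seed = 5)
  three <- intersect_targets(
    db$component_targets,
    filter_disease_targets(db$disease_targets),
    db$metabolite_targets
  )
  expect_equal(three, sort(db$truth$planted_critical_targets))
  db0 <- generate_target_databases(n_planted_critical = 0, seed = 5)
  expect_length(intersect_targets(
    db0$component_targets, filter_disease_targets(db0$disease_targets),
    db0$metabolite_targets
  ), 0)
})

test_that("planted hubs pass the centrality screen and decoys do not", {
  db <- generate_target_databases(seed = 6)
  common <- intersect_targets(db$component_targets,
                              filter_disease_targets(db$disease_targets))
  g <- build_ppi(db$ppi_edges, node_whitelist = common)
  crit <- screen_critical_targets(centralities(g))
  expect_setequal(crit, db$truth$planted_critical_targets)
})

test_that("pipeline inputs are written completely with a manifest", {
  dir <- withr::local_tempdir()
  out <- write_pipeline_inputs(dir, sim_config(n_features = 40, seed = 3))
  for (p in out[setdiff(names(out), "truth")]) expect_true(file.exists(p))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$config$n_features, 40)
  expect_length(manifest$truth$planted_critical_targets, 6)
  # round-trip the peak table
  tab <- read_feature_table(file.path(dir, "feature_table.tsv"))
  expect_equal(dim(tab)[1], 40)
})
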