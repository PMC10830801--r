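test_that("PCA recovers rank structure and reconstructs exactly", {
  set.seed(3)
  u <- stats::rnorm(10)
  v <- stats::rnorm(6)
  rank1 <- outer(u, v)
  fit <- pca(rank1, k = 2)
  expect_equal(fit$explained[1], 1, tolerance = 1e-12)
  x <- matrix(stats::rnorm(8 * 5), 8)
  full <- pca(x, k = 5)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(full$scores %*% t(full$loadings), xc, tolerance = 1e-10)
  expect_lte(sum(full$explained), 1 + 1e-12)
  expect_error(pca(x, k = 9), "exceeds")
})

test_that("class encoding gives centered indicators", {
  y <- encode_classes(c("N", "N", "D", "D"))
  expect_identical(as.vector(y) + 0.5, c(1, 1, 0, 0, 0, 0, 1, 1))
  expect_equal(unname(colSums(y)), c(0, 0))
  y3 <- encode_classes(rep(c("N", "D", "H"), 2))
  expect_equal(ncol(y3), 3)
  expect_equal(unname(rowSums(y3 + 1 / 3)), rep(1, 6))
  expect_error(encode_classes(rep("N", 4)), "two classes")
})

test_that("with no orthogonal components the fit equals a textbook PLS2", {
  set.seed(11)
  for (i in 1:5) {
    g <- rep(c("N", "D", "H"), each = 6)
    x <- matrix(stats::rnorm(18 * 30), 18)
    x[, 1] <- x[, 1] + 2 * (g == "D")
    m <- fit_opls_da(x, g, n_orth = 0, scaling = "uv")
    xs <- scale(x)
    r2_oracle <- oracle_pls2(xs, encode_classes(g), ncomp = 2)
    expect_equal(m$r2y, r2_oracle, tolerance = 1e-8)
  }
})

test_that("an exactly class-determined column gives R2Y = 1", {
  g <- rep(c("N", "D"), each = 5)
  x <- cbind(as.numeric(g == "D"), 0.5 * as.numeric(g == "D"))
  m <- fit_opls_da(x, g, n_pred = 1, n_orth = 0, scaling = "center")
  expect_equal(m$r2y, 1, tolerance = 1e-12)
})

test_that("jointly permuting samples leaves R2Y unchanged", {
  set.seed(21)
  g <- rep(c("N", "D", "H"), each = 6)
  x <- matrix(stats::rnorm(18 * 25), 18)
  x[, 1:3] <- x[, 1:3] + outer(as.numeric(g == "D"), c(3, 2, 1))
  m1 <- fit_opls_da(x, g, n_orth = 1, scaling = "uv")
  perm <- sample(18)
  m2 <- fit_opls_da(x[perm, ], g[perm], n_orth = 1, scaling = "uv")
  expect_equal(m1$r2y, m2$r2y, tolerance = 1e-9)
})

test_that("scores are mutually orthogonal and VIP satisfies its identity", {
  sim <- generate_feature_table(sim_config(n_features = 120, seed = 9))
  proc <- preprocess_features(sim$table, scaling = NULL)
  m <- opls_da(proc, n_orth = 2)
  t1 <- m$t[[1]]
  t2 <- m$t[[2]]
  expect_lt(abs(sum(t1 * t2)), 1e-8 * sqrt(sum(t1^2) * sum(t2^2)))
  for (to in m$t_orth) {
    expect_lt(abs(sum(t1 * to)), 1e-8 * sqrt(sum(t1^2) * sum(to^2)))
    expect_lt(abs(sum(t2 * to)), 1e-8 * sqrt(sum(t2^2) * sum(to^2)))
  }
  v <- vip(m)
  expect_true(all(v$vip >= 0))
  expect_equal(sum(v$vip^2), nrow(v), tolerance = 1e-6 * nrow(v))
  vc <- vip(m, "combined")
  expect_equal(sum(vc$vip^2), nrow(vc), tolerance = 1e-6 * nrow(vc))
})

test_that("a single component with equal weights gives all VIP = 1", {
  g <- rep(c("N", "D"), each = 6)
  base <- as.numeric(g == "D")
  x <- cbind(base, base, base, base) + matrix(stats::rnorm(48, sd = 1e-6), 12)
  m <- fit_opls_da(x, g, n_pred = 1, n_orth = 0, scaling = "uv")
  expect_equal(vip(m)$vip, rep(1, 4), tolerance = 1e-3)
})

test_that("planted discriminant features rank in the top VIP decile", {
  sim <- generate_feature_table(sim_config(seed = 4))
  proc <- preprocess_features(sim$table, scaling = NULL)
  m <- opls_da(proc)
  v <- vip(m)
  decile <- v$feature_id[order(-v$vip)][seq_len(ceiling(nrow(v) / 10))]
  expect_true(all(sim$truth$differential_feature_ids %in% decile))
})

test_that("Q2 respects the optimism inequality and separates signal from null", {
  set.seed(31)
  null_q2 <- replicate(12, {
    g <- rep(c("N", "D", "H"), each = 6)
    x <- matrix(stats::rnorm(18 * 40), 18)
    q2_crossval(x, g, n_pred = 2, n_orth = 0)
  })
  # chance-level Q2 stays near or below zero
  expect_gte(mean(null_q2 <= 0.2), 0.9)
  sim <- generate_feature_table(sim_config(seed = 6, cv_noise = 0.1))
  proc <- preprocess_features(sim$table, scaling = NULL)
  m <- opls_da(proc)
  expect_gt(m$q2, 0.3)
  expect_lte(m$q2, m$r2y + 0.05)
  expect_gt(m$q2, max(null_q2))
})

test_that("a fold emptying a class is rejected", {
  g <- c("N", rep("D", 9))
  x <- matrix(stats::rnorm(10 * 5), 10)
  expect_error(q2_crossval(x, g, n_pred = 1, folds = 7), "class")
})

test_that("permutation test separates a planted model from label noise", {
  sim <- generate_feature_table(sim_config(n_features = 150, seed = 8))
  proc <- preprocess_features(sim$table, scaling = NULL)
  m <- opls_da(proc)
  perm <- permutation_test(m, n_perm = 49, seed = 2)
  expect_equal(nrow(perm$permutations), 49)
  expect_true(all(perm$permutations$q2 < m$q2))
  expect_lt(perm$q2_intercept, m$q2)
  expect_lt(perm$r2_intercept, m$r2y)
  expect_true(perm$valid)
  # determinism of the seeded shuffles
  perm2 <- permutation_test(m, n_perm = 49, seed = 2)
  expect_equal(perm$permutations, perm2$permutations)
})

test_that("refitting with unshuffled labels reproduces the model exactly", {
  set.seed(41)
  g <- rep(c("N", "D", "H"), each = 6)
  x <- matrix(stats::rnorm(18 * 20), 18)
  x[, 1] <- x[, 1] + 2 * (g == "D")
  m <- fit_opls_da(x, g, n_orth = 0, scaling = "uv")
  refit <- fit_opls_da(x, g, n_pred = m$n_pred, n_orth = 0, scaling = "uv")
  expect_equal(refit$r2y, m$r2y, tolerance = 1e-12)
})

test_that("tidy and glance expose model quantities", {
  sim <- generate_feature_table(sim_config(n_features = 60, seed = 10))
  proc <- preprocess_features(sim$table, scaling = NULL)
  m <- opls_da(proc, n_orth = 1)
  td <- tidy(m)
  expect_true(all(c("feature_id", "w1", "p1", "vip") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_orth, 1)
  expect_true(gl$r2y >= 0 && gl$r2y <= 1)
  sc <- opls_scores(m)
  expect_equal(nrow(sc), 24)
  pred <- predict(m, t(subset_groups(log10_transform(impute_half_minimum(
    filter_by_detection(filter_by_rt(sim$table)))), c("N", "D", "H"))$intensities))
  expect_equal(nrow(pred), 24)
})
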