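test_that("exact Mann-Whitney p matches full enumeration", {
  mw <- mann_whitney_u(1:3, 4:6)
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(oracle_mw_exact(1:3, 4:6), 0.1)
  set.seed(5)
  for (i in 1:10) {
    x <- stats::rnorm(3)
    y <- stats::rnorm(3)
    expect_equal(mann_whitney_u(x, y, "exact")$p, oracle_mw_exact(x, y))
  }
  for (i in 1:5) {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8, mean = 1)
    expect_equal(mann_whitney_u(x, y, "exact")$p, oracle_mw_exact(x, y))
  }
})

test_that("U test is symmetric in its degenerate and swapped forms", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  expect_equal(mann_whitney_u(x, x, "exact")$p, 1.0)
  y <- c(2.2, 4.4, 8.8, 9.9)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$p, b$p)
  expect_equal(b$u, length(x) * length(y) - a$u)
  expect_error(mann_whitney_u(numeric(), y), "empty")
})

test_that("asymptotic p stays within 0.02 of exact for tie-free 8 vs 8", {
  set.seed(12)
  for (i in 1:100) {
    x <- stats::rnorm(8)
    y <- stats::rnorm(8, mean = stats::runif(1, 0, 2))
    pe <- mann_whitney_u(x, y, "exact")$p
    pa <- mann_whitney_u(x, y, "asymptotic")$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("fold change is the ratio of raw-scale means", {
  expect_equal(fold_change(c(200, 300, 400), c(50, 100, 150)), 3)
  expect_equal(fold_change(1:10, 1:10), 1)
  expect_error(fold_change(1:3, c(-2, 0, 2)), "positive")
})

test_that("recovery flag follows the sign logic of treated-group retracement", {
  expect_equal(recovery_flag(100, 300, 180), list(recovery = "Y", direction = "D"))
  expect_equal(recovery_flag(100, 30, 60), list(recovery = "Y", direction = "U"))
  expect_equal(recovery_flag(100, 300, 400), list(recovery = "N", direction = "U"))
  expect_equal(recovery_flag(100, 300, 300), list(recovery = "N", direction = "D"))
  # optional minimum-restoration fraction
  expect_equal(recovery_flag(100, 300, 295, min_restoration = 0.2)$recovery, "N")
  expect_equal(recovery_flag(100, 300, 200, min_restoration = 0.2)$recovery, "Y")
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(8)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the cascade applies its stages in order with strict thresholds", {
  # 4 features engineered per stage: low VIP, high p, no recovery, survivor
  x <- rbind(
    c(rep(100, 8), rep(300, 8), rep(150, 8)),  # F001 differential, recovers
    c(rep(100, 8), rep(300, 8), rep(150, 8)),  # F002 same but VIP below cut
    rep(c(100, 140), 12),                      # F003 no N/D difference
    c(rep(100, 8), rep(300, 8), rep(400, 8))   # F004 moves further away
  )
  set.seed(2)
  x <- x * exp(matrix(stats::rnorm(length(x), sd = 0.02), nrow(x)))
  tab <- make_table(x, groups = rep(c("N", "D", "H"), each = 8))
  vips <- tibble::tibble(feature_id = sprintf("F%03d", 1:4),
                         vip = c(2.0, 1.4, 1.9, 1.8))
  rec <- screen_cascade(tab, vips)
  rec <- rec[order(rec$feature_id), ]
  expect_equal(rec$passed_stage, c(4L, 0L, 1L, 2L))
  expect_equal(rec$selected, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rec$recovery[1], "Y")
  expect_equal(rec$direction[1], "D")
  expect_gt(rec$fold_change[1], 2.5)
  # the FDR family is exactly the stage-3 survivors
  expect_equal(attr(rec, "thresholds")$fdr_family_size, 1L)
  expect_true(is.na(rec$adjusted_p[2]))
})

test_that("FDR is computed over stage-3 survivors with their count as family", {
  sim <- generate_feature_table(sim_config(seed = 13))
  proc <- preprocess_features(sim$table, log10 = FALSE, scaling = NULL)
  m <- opls_da(log10_transform(proc))
  rec <- screen_cascade(proc, vip(m))
  fam <- attr(rec, "thresholds")$fdr_family_size
  surv <- rec[rec$passed_stage >= 3, ]
  expect_equal(nrow(surv), fam)
  expect_equal(sort(surv$adjusted_p), sort(oracle_bh(surv$raw_p)))
  log <- attr(rec, "log")
  expect_equal(log$features_before[4], fam)
  expect_true(all(log$features_after <= log$features_before))
})

test_that("tightening any threshold never grows the surviving set", {
  sim <- generate_feature_table(sim_config(seed = 14))
  proc <- preprocess_features(sim$table, log10 = FALSE, scaling = NULL)
  m <- opls_da(log10_transform(proc))
  v <- vip(m)
  base <- screen_cascade(proc, v)
  sel_base <- base$feature_id[base$selected]
  for (args in list(list(vip_min = 2), list(p_max = 0.01), list(fdr_max = 0.01))) {
    tight <- do.call(screen_cascade, c(list(proc, v), args))
    expect_true(all(tight$feature_id[tight$selected] %in% sel_base))
  }
})

test_that("rank-based screening is unchanged by the log transform", {
  sim <- generate_feature_table(sim_config(n_features = 60, seed = 15))
  proc <- preprocess_features(sim$table, log10 = FALSE, scaling = NULL)
  v <- tibble::tibble(feature_id = proc$feature_meta$feature_id, vip = 2)
  p_raw <- screen_cascade(proc, v)$raw_p
  p_log <- screen_cascade(log10_transform(proc), v)$raw_p
  expect_equal(sort(p_raw), sort(p_log))
})
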