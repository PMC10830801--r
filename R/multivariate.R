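# PCA, class encoding, and multiclass OPLS-DA with VIP, cross-validated Q2
# and label-permutation validation. The discriminant model uses the
# orthogonal-filtering-then-PLS2 formulation: structured X-variation
# orthogonal to the class-indicator subspace is removed component by
# component, then a standard PLS2 (NIPALS) fit with n_classes - 1 predictive
# components is run on the filtered matrix.

#' Principal component analysis by SVD
#'
#' @param x Samples x features numeric matrix (scale beforehand as desired;
#'   columns are mean-centered here).
#' @param k Number of components (`k <= min(dim(x))`).
#' @return List with `scores` (U * S, samples x k), `loadings` (orthonormal,
#'   features x k) and `explained` (variance fractions, length k).
#' @export
pca <- function(x, k = 2) {
  x <- as.matrix(x)
  if (k > min(dim(x))) abort("k exceeds matrix rank bound")
  xc <- sweep(x, 2, colMeans(x))
  s <- svd(xc)
  list(
    scores = s$u[, seq_len(k), drop = FALSE] %*% diag(s$d[seq_len(k)], k, k),
    loadings = s$v[, seq_len(k), drop = FALSE],
    explained = (s$d^2 / sum(s$d^2))[seq_len(k)]
  )
}

#' PCA scores of a feature table
#'
#' Transposes to samples x features, runs [pca()], and returns a tibble of
#' scores joined to group labels (QC samples included, as in instrument
#' stability checks).
#'
#' @param table A processed (scaled) [feature_table()].
#' @param k Number of components.
#' @return Tibble `sample_id`, `group`, `PC1..PCk`, with attribute
#'   `explained`.
#' @export
pca_scores <- function(table, k = 2) {
  stopifnot(inherits(table, "feature_table"))
  fit <- pca(t(table$intensities), k = k)
  scores <- tibble::as_tibble(fit$scores, .name_repair = ~ paste0("PC", seq_len(k)))
  out <- dplyr::bind_cols(table$sample_meta[, c("sample_id", "group")], scores)
  attr(out, "explained") <- fit$explained
  out
}

#' Class-indicator encoding
#'
#' One column per class, 1/0 membership, then column-centered (the numeric Y
#' a PLS-family classifier regresses on).
#'
#' @param groups Character or factor vector of class labels (>= 2 classes).
#' @return Centered indicator matrix with attributes `levels` and
#'   `col_means`.
#' @export
encode_classes <- function(groups) {
  groups <- as.character(groups)
  levels <- unique(groups)
  if (length(levels) < 2) abort("need at least two classes")
  y <- vapply(levels, function(l) as.numeric(groups == l), numeric(length(groups)))
  mns <- colMeans(y)
  yc <- sweep(y, 2, mns)
  colnames(yc) <- levels
  attr(yc, "levels") <- levels
  attr(yc, "col_means") <- mns
  yc
}

# --- core fitter -----------------------------------------------------------

# PLS2 weight from the current X/Y cross-product (first left singular vector)
pls_weight <- function(x, y) {
  s <- crossprod(x, y)
  svd(s, nu = 1, nv = 0)$u[, 1]
}

# one NIPALS PLS2 component; returns w, t, p, q and deflated matrices
nipals_component <- function(x, y, tol = 1e-10, max_iter = 200) {
  u <- y[, which.max(apply(y, 2, var))]
  if (all(u == 0)) u <- y[, 1]
  w <- NULL
  for (i in seq_len(max_iter)) {
    w_new <- crossprod(x, u)
    w_new <- w_new / sqrt(sum(w_new^2))
    t <- x %*% w_new
    q <- crossprod(y, t) / c(crossprod(t))
    u_new <- y %*% q / c(crossprod(q))
    if (!is.null(w) && sqrt(sum((w_new - w)^2)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
    u <- u_new
  }
  t <- x %*% w
  p <- crossprod(x, t) / c(crossprod(t))
  q <- crossprod(y, t) / c(crossprod(t))
  list(w = c(w), t = c(t), p = c(p), q = c(q))
}

# fixed-component OPLS-DA fit on scaled X and centered Y
fit_opls_core <- function(x, y, n_pred, n_orth) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  ssx_tot <- sum(x^2)
  ssy_tot <- sum(y^2)
  if (ssx_tot == 0) abort("X has zero variance after scaling")
  w_o <- t_o <- p_o <- list()
  xd <- x
  for (j in seq_len(n_orth)) {
    s <- crossprod(xd, y)
    w <- svd(s, nu = 1, nv = 0)$u[, 1]
    t <- xd %*% w
    p <- crossprod(xd, t) / c(crossprod(t))
    # component of the loading orthogonal to the Y-predictive weight space
    # (centered indicator Y makes X'Y rank-deficient, so project onto an
    # orthonormal basis rather than inverting the Gram matrix)
    qs <- qr(s)
    basis <- qr.Q(qs)[, seq_len(qs$rank), drop = FALSE]
    proj <- basis %*% crossprod(basis, p)
    wo <- p - proj
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-10) break
    wo <- wo / nrm
    to <- xd %*% wo
    po <- crossprod(xd, to) / c(crossprod(to))
    xd <- xd - to %*% t(po)
    w_o[[j]] <- c(wo)
    t_o[[j]] <- c(to)
    p_o[[j]] <- c(po)
  }
  w_p <- t_p <- p_p <- q_p <- list()
  ss_y <- numeric(0)
  yd <- y
  for (a in seq_len(n_pred)) {
    comp <- nipals_component(xd, yd)
    xd <- xd - comp$t %*% t(comp$p)
    yd <- yd - comp$t %*% t(comp$q)
    w_p[[a]] <- comp$w
    t_p[[a]] <- comp$t
    p_p[[a]] <- comp$p
    q_p[[a]] <- comp$q
    ss_y[a] <- c(crossprod(comp$t)) * sum(comp$q^2)
  }
  tp <- do.call(cbind, t_p)
  qp <- do.call(cbind, q_p)
  yhat <- tp %*% t(qp)
  list(
    w = w_p, t = t_p, p = p_p, q = q_p, ss = ss_y,
    w_orth = w_o, t_orth = t_o, p_orth = p_o,
    n_pred = length(w_p), n_orth = length(w_o),
    r2y = 1 - sum((y - yhat)^2) / ssy_tot,
    r2x = 1 - sum(xd^2) / ssx_tot,
    yhat = yhat
  )
}

# project new (already scaled) samples through a fitted core model
predict_opls_core <- function(core, xnew) {
  xnew <- as.matrix(xnew)
  for (j in seq_len(core$n_orth)) {
    to <- xnew %*% core$w_orth[[j]]
    xnew <- xnew - to %*% t(core$p_orth[[j]])
  }
  tp <- matrix(0, nrow(xnew), core$n_pred)
  for (a in seq_len(core$n_pred)) {
    tp[, a] <- xnew %*% core$w[[a]]
    xnew <- xnew - tp[, a, drop = FALSE] %*% t(core$p[[a]])
  }
  qp <- do.call(cbind, core$q)
  list(scores = tp, yhat = tp %*% t(qp))
}

scaling_params <- function(x, method) {
  ctr <- colMeans(x)
  s <- apply(x, 2, sd)
  scl <- switch(method,
    center = rep(1, length(s)),
    uv = ifelse(s == 0, 1, s),
    pareto = ifelse(s == 0, 1, sqrt(s))
  )
  list(center = ctr, scale = scl)
}

# venetian-blind fold ids, assigned by sample order within class
venetian_folds <- function(groups, folds) {
  ids <- integer(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ids[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  ids
}

#' Cross-validated Q2 of an OPLS-DA model specification
#'
#' Class-stratified venetian-blind folds (assignment by sample order within
#' class; deterministic). Each fold rescales on the training samples, fits
#' the fixed-size model, and predicts the left-out samples;
#' `Q2 = 1 - PRESS / SS_Y` with `SS_Y` the total centered indicator
#' variance.
#'
#' @param x Samples x features matrix, unscaled (scaling is refit per fold).
#' @param groups Class labels (length `nrow(x)`).
#' @param n_pred,n_orth Component counts of the model specification.
#' @param folds Number of cross-validation segments.
#' @param scaling Scaling method (see [scale_features()]).
#' @return Q2 (scalar).
#' @export
q2_crossval <- function(x, groups, n_pred = NULL, n_orth = 0, folds = 7,
                        scaling = "pareto") {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (folds < 2) abort("folds must be >= 2")
  n_pred <- n_pred %||% (length(unique(groups)) - 1L)
  fold_id <- venetian_folds(groups, folds)
  # more folds than samples per class leaves trailing folds empty; they are
  # simply skipped (equivalent to leave-one-out within the class)
  y_full <- encode_classes(groups)
  ss_tot <- sum(y_full^2)
  press <- 0
  for (f in sort(unique(fold_id))) {
    test <- fold_id == f
    gtrain <- groups[test == FALSE]
    if (length(unique(gtrain)) < length(unique(groups))) {
      abort("a fold empties a class; reduce folds")
    }
    sp <- scaling_params(x[!test, , drop = FALSE], scaling)
    xtr <- apply_scaling_cols(x[!test, , drop = FALSE], sp)
    xte <- apply_scaling_cols(x[test, , drop = FALSE], sp)
    levels <- unique(groups)
    ytr_raw <- vapply(levels, function(l) as.numeric(gtrain == l),
                      numeric(length(gtrain)))
    ymeans <- colMeans(ytr_raw)
    ytr <- sweep(ytr_raw, 2, ymeans)
    core <- fit_opls_core(xtr, ytr, n_pred, n_orth)
    yte_raw <- vapply(levels, function(l) as.numeric(groups[test] == l),
                      numeric(sum(test)))
    yte <- sweep(matrix(yte_raw, nrow = sum(test)), 2, ymeans)
    pred <- predict_opls_core(core, xte)
    press <- press + sum((yte - pred$yhat)^2)
  }
  1 - press / ss_tot
}

apply_scaling_cols <- function(x, sp) {
  sweep(sweep(x, 2, sp$center, "-"), 2, sp$scale, "/")
}

#' Fit a multiclass OPLS-DA model
#'
#' @param x Samples x features matrix on the modeling scale (e.g. log10
#'   intensities), unscaled: scaling is part of the model so that
#'   cross-validation can refit it per fold.
#' @param groups Class labels, one per row of `x`.
#' @param n_pred Number of predictive components (default classes - 1).
#' @param n_orth Number of orthogonal components, or `"auto"` (default): add
#'   an orthogonal component while seven-fold Q2 improves by more than 0.01,
#'   up to `max_orth`.
#' @param scaling Scaling method (`"uv"`, `"center"`, `"pareto"`).
#' @param folds Cross-validation segments for Q2 (venetian blind).
#' @param max_orth Cap on orthogonal components under `"auto"`.
#' @return An `opls_model`: component vectors (predictive weights/scores/
#'   loadings/Y-loadings, orthogonal counterparts), per-component explained
#'   Y-variance `ss`, `R2X`, `R2Y`, `Q2`, the class encoding, and the
#'   training data needed for permutation refits.
#' @export
fit_opls_da <- function(x, groups, n_pred = NULL, n_orth = "auto",
                        scaling = "pareto", folds = 7, max_orth = 5) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (nrow(x) != length(groups)) abort("groups must match rows of x")
  n_classes <- length(unique(groups))
  if (nrow(x) < n_classes + 1) abort("need at least classes + 1 samples")
  n_pred <- n_pred %||% (n_classes - 1L)
  q2_per_orth <- numeric(0)
  if (identical(n_orth, "auto")) {
    best_q2 <- q2_crossval(x, groups, n_pred, 0, folds, scaling)
    q2_per_orth <- best_q2
    n_orth <- 0L
    while (n_orth < max_orth) {
      q2_next <- q2_crossval(x, groups, n_pred, n_orth + 1L, folds, scaling)
      q2_per_orth <- c(q2_per_orth, q2_next)
      if (q2_next - best_q2 <= 0.01) break
      best_q2 <- q2_next
      n_orth <- n_orth + 1L
    }
  }
  sp <- scaling_params(x, scaling)
  xs <- apply_scaling_cols(x, sp)
  y <- encode_classes(groups)
  core <- fit_opls_core(xs, y, n_pred, n_orth)
  q2 <- q2_crossval(x, groups, n_pred, core$n_orth, folds, scaling)
  structure(
    c(core, list(
      x = x, groups = groups, y = y,
      scaling = sp, scaling_method = scaling, folds = folds,
      q2 = q2, q2_per_orth = q2_per_orth,
      levels = attr(y, "levels"),
      feature_ids = colnames(x) %||% paste0("V", seq_len(ncol(x))),
      sample_ids = rownames(x) %||% paste0("S", seq_len(nrow(x)))
    )),
    class = "opls_model"
  )
}

#' Fit OPLS-DA directly from a feature table
#'
#' Subsets to the requested groups, transposes to samples x features, and
#' fits [fit_opls_da()]. Expects a log-transformed but unscaled table.
#'
#' @param table A [feature_table()].
#' @param groups Groups to model (default `c("N", "D", "H")`).
#' @param ... Passed to [fit_opls_da()].
#' @return An `opls_model`.
#' @export
opls_da <- function(table, groups = c("N", "D", "H"), ...) {
  stopifnot(inherits(table, "feature_table"))
  sub <- subset_groups(table, groups)
  fit_opls_da(t(sub$intensities), sub$sample_meta$group, ...)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "<opls_model> %d+%d components, %d classes (%s)\nR2X = %.3f  R2Y = %.3f  Q2 = %.3f\n",
    x$n_pred, x$n_orth, length(x$levels), paste(x$levels, collapse = ", "),
    x$r2x, x$r2y, x$q2
  ))
  invisible(x)
}

#' Predict class membership for new samples
#'
#' @param object An `opls_model`.
#' @param newdata Samples x features matrix on the training (unscaled)
#'   scale.
#' @param ... Unused.
#' @return Tibble with predictive scores, fitted indicator values and the
#'   predicted class (nearest indicator column).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  xs <- apply_scaling_cols(as.matrix(newdata), object$scaling)
  pred <- predict_opls_core(object, xs)
  yhat <- sweep(pred$yhat, 2, attr(object$y, "col_means"), "+")
  cls <- object$levels[apply(yhat, 1, which.max)]
  out <- tibble::as_tibble(
    pred$scores, .name_repair = ~ paste0("t", seq_len(object$n_pred))
  )
  out$class <- cls
  out
}

#' Variable influence on projection
#'
#' `VIP_j = sqrt(p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a)` over the
#' predictive components (default), where `SS_a` is the Y-variance explained
#' by component a and p the feature count; `sum(VIP^2) = p` by construction.
#' The `"combined"` variant additionally weighs orthogonal components by
#' their explained X-variance.
#'
#' @param model A fitted `opls_model`.
#' @param variant `"pred"` (predictive components only, default) or
#'   `"combined"`.
#' @return Tibble `feature_id`, `vip`.
#' @export
vip <- function(model, variant = c("pred", "combined")) {
  variant <- match.arg(variant)
  stopifnot(inherits(model, "opls_model"), model$n_pred >= 1)
  p <- length(model$feature_ids)
  wn2 <- function(w) (w / sqrt(sum(w^2)))^2
  num <- rep(0, p)
  denom <- 0
  for (a in seq_len(model$n_pred)) {
    num <- num + model$ss[a] * wn2(model$w[[a]])
    denom <- denom + model$ss[a]
  }
  if (variant == "combined" && model$n_orth > 0) {
    for (j in seq_len(model$n_orth)) {
      ssx_o <- c(crossprod(model$t_orth[[j]])) * sum(model$p_orth[[j]]^2)
      num <- num + ssx_o * wn2(model$w_orth[[j]])
      denom <- denom + ssx_o
    }
  }
  tibble::tibble(feature_id = model$feature_ids, vip = sqrt(p * num / denom))
}

#' Label-permutation validity test
#'
#' Refits the model `n_perm` times with class labels shuffled, recording
#' `(R2Y, Q2, r)` where `r` is the mean absolute column-wise Pearson
#' correlation between the permuted and original indicator matrices.
#' Least-squares lines of R2Y and Q2 versus `r` are fit through all
#' `n_perm + 1` points (the unpermuted model sits at `r = 1`); the reported
#' intercepts at `r = 0` estimate the chance-level fit. The model is `valid`
#' when both intercepts lie below the real model's values and the Q2
#' intercept is below 0.05.
#'
#' @param model A fitted `opls_model`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for the label shuffles.
#' @return A `permutation_result`: tibble of permuted triples plus
#'   intercepts and validity flag.
#' @export
permutation_test <- function(model, n_perm = 999, seed = 1) {
  stopifnot(inherits(model, "opls_model"))
  if (n_perm < 1) abort("n_perm must be >= 1")
  set.seed(seed)
  y0 <- model$y
  res <- purrr::map_dfr(seq_len(n_perm), function(i) {
    perm <- sample(nrow(model$x))
    gperm <- model$groups[perm]
    sp <- model$scaling
    xs <- apply_scaling_cols(model$x, sp)
    yp <- encode_classes(gperm)
    core <- fit_opls_core(xs, yp, model$n_pred, model$n_orth)
    q2 <- q2_crossval(model$x, gperm, model$n_pred, model$n_orth,
                      model$folds, model$scaling_method)
    r <- mean(abs(diag(cor(yp[, model$levels, drop = FALSE],
                           y0[, model$levels, drop = FALSE]))))
    tibble::tibble(perm = i, r = r, r2y = core$r2y, q2 = q2)
  })
  pts <- dplyr::bind_rows(
    res[, c("r", "r2y", "q2")],
    tibble::tibble(r = 1, r2y = model$r2y, q2 = model$q2)
  )
  r2_int <- unname(coef(lm(r2y ~ r, data = pts))[1])
  q2_int <- unname(coef(lm(q2 ~ r, data = pts))[1])
  structure(
    list(
      permutations = res, n_perm = n_perm,
      r2_intercept = r2_int, q2_intercept = q2_int,
      real_r2y = model$r2y, real_q2 = model$q2,
      valid = r2_int < model$r2y && q2_int < model$q2 && q2_int < 0.05
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d permutations\nR2 intercept = %.3f (real %.3f)  Q2 intercept = %.3f (real %.3f)\nvalid: %s\n",
    x$n_perm, x$r2_intercept, x$real_r2y, x$q2_intercept, x$real_q2, x$valid
  ))
  invisible(x)
}

# --- broom-style accessors -------------------------------------------------

#' Tidy an OPLS-DA model
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return Per-feature tibble: predictive weights/loadings of each component
#'   and the VIP score.
#' @export
tidy.opls_model <- function(x, ...) {
  out <- tibble::tibble(feature_id = x$feature_ids)
  for (a in seq_len(x$n_pred)) {
    out[[paste0("w", a)]] <- x$w[[a]]
    out[[paste0("p", a)]] <- x$p[[a]]
  }
  dplyr::left_join(out, vip(x), by = "feature_id")
}

#' Model-level OPLS-DA diagnostics
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @return One-row tibble: `n_pred`, `n_orth`, `r2x`, `r2y`, `q2`.
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(
    n_pred = x$n_pred, n_orth = x$n_orth,
    r2x = x$r2x, r2y = x$r2y, q2 = x$q2
  )
}

#' Tidy a permutation result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble of `(perm, r, r2y, q2)` triples.
#' @export
tidy.permutation_result <- function(x, ...) x$permutations

#' Summarize a permutation result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return One-row tibble with intercepts, real values and the validity
#'   flag.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    n_perm = x$n_perm,
    r2_intercept = x$r2_intercept, q2_intercept = x$q2_intercept,
    real_r2y = x$real_r2y, real_q2 = x$real_q2, valid = x$valid
  )
}

#' Scores of an OPLS-DA model as a tibble
#'
#' @param model An `opls_model`.
#' @return Tibble `sample_id`, `group`, predictive scores `t1..`, first
#'   orthogonal score `to1` when present.
#' @export
opls_scores <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  out <- tibble::tibble(sample_id = model$sample_ids, group = model$groups)
  for (a in seq_len(model$n_pred)) out[[paste0("t", a)]] <- model$t[[a]]
  if (model$n_orth > 0) out$to1 <- model$t_orth[[1]]
  out
}
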