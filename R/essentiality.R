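#' Standardize feature columns
#'
#' Centers and scales each feature to zero mean, unit variance. When
#' `center`/`scale` vectors are supplied (training-fold statistics) they are
#' applied as-is, so test folds are transformed without leakage. Zero-variance
#' features are dropped with a warning.
#'
#' @param x numeric matrix or data.frame of features.
#' @param center,scale optional named statistics to apply.
#' @return list(x = standardized matrix, center, scale).
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    zero <- scale == 0 | is.na(scale)
    if (any(zero)) {
      warning("dropping zero-variance feature(s): ",
              paste(colnames(x)[zero], collapse = ", "))
      x <- x[, !zero, drop = FALSE]
      center <- center[!zero]; scale <- scale[!zero]
    }
  } else {
    x <- x[, names(center), drop = FALSE]
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"), center = center, scale = scale)
}

balanced_accuracy <- function(truth, pred) {
  sens <- if (any(truth == 1)) mean(pred[truth == 1] == 1) else NA_real_
  spec <- if (any(truth == 0)) mean(pred[truth == 0] == 0) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

# Stratified k-fold assignment: within each class, rows are dealt round-robin
# after a seeded shuffle.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# L1 logistic fits for all C values at once via glmnet's lambda path.
# C is the inverse regularization strength; lambda = 1 / (n * C).
lasso_path_fit <- function(x, y, c_grid) {
  lam <- 1 / (nrow(x) * c_grid)
  ord <- order(lam, decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = lam[ord], standardize = FALSE,
                        thresh = 1e-9, maxit = 1e6)
  list(fit = fit, lambda = lam, order = ord)
}

#' Cross-validated L1 logistic classification of essentiality
#'
#' Five-fold (default) stratified cross-validation of an L1-penalised
#' logistic regression of the essentiality label on the NCLE feature table,
#' across a grid of inverse regularization strengths C (default: 1e-5 to 10
#' in 1000 evenly spaced steps; `grid_scale = "log"` is available). Features
#' are standardized inside each training fold and the fold statistics applied
#' to the held-out fold. Performance is balanced accuracy at a 0.5 posterior
#' threshold, averaged over folds. The optimal C maximises balanced accuracy
#' with the fewest non-zero coefficients (ties: smaller C).
#'
#' @param features data.frame/matrix of numeric features (one row per
#'   protein).
#' @param labels 0/1 essentiality labels.
#' @param k folds (default 5).
#' @param c_grid inverse regularization strengths; default
#'   `seq(1e-5, 10, length.out = n_c)`.
#' @param n_c grid size when `c_grid` is NULL (default 1000).
#' @param grid_scale "linear" (default) or "log".
#' @param seed RNG seed for fold assignment.
#' @return `lasso_cv_result`: list with c_grid, balanced_accuracy_mean,
#'   nonzero_features (count per C), selected_C, selected_features (names at
#'   selected C, refit on the full data), folds.
#' @export
lasso_cv <- function(features, labels, k = 5, c_grid = NULL, n_c = 1000,
                     grid_scale = c("linear", "log"), seed = 1) {
  grid_scale <- match.arg(grid_scale)
  x <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (min(table(y)) < k) stop("need at least k members per class")
  if (is.null(c_grid)) {
    c_grid <- if (grid_scale == "linear") seq(1e-5, 10, length.out = n_c)
    else exp(seq(log(1e-5), log(10), length.out = n_c))
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- stratified_folds(y, k)
  ba <- matrix(NA_real_, k, length(c_grid))
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    st <- standardize(x[tr, , drop = FALSE])
    path <- lasso_path_fit(st$x, y[tr], c_grid)
    xt <- standardize(x[te, , drop = FALSE], st$center, st$scale)$x
    pr <- stats::predict(path$fit, newx = xt, type = "response")
    # columns of pr follow path$order (decreasing lambda)
    inv <- match(seq_along(c_grid), path$order)
    pred <- pr[, inv, drop = FALSE] >= 0.5
    ba[f, ] <- apply(pred, 2, function(p) balanced_accuracy(y[te], as.integer(p)))
  }
  ba_mean <- colMeans(ba)
  # non-zero counts from a full-data fit (the model one would report)
  st_all <- standardize(x)
  path_all <- lasso_path_fit(st_all$x, y, c_grid)
  bmat <- as.matrix(path_all$fit$beta)
  inv <- match(seq_along(c_grid), path_all$order)
  nz <- colSums(bmat[, inv, drop = FALSE] != 0)
  res <- structure(list(c_grid = c_grid, balanced_accuracy_mean = ba_mean,
                        nonzero_features = nz, folds = fold,
                        beta = bmat[, inv, drop = FALSE],
                        feature_names = colnames(st_all$x)),
                   class = "lasso_cv_result")
  res$selected_C <- select_optimal_C(res)
  sel <- which(c_grid == res$selected_C)[1]
  res$selected_features <- res$feature_names[bmat[, inv[sel]] != 0]
  res
}

#' @export
print.lasso_cv_result <- function(x, ...) {
  cat(sprintf("<lasso_cv_result> %d C values; best mean balanced accuracy %.3f\n",
              length(x$c_grid), max(x$balanced_accuracy_mean)))
  cat(sprintf("  selected C = %g with %d non-zero feature(s)%s\n",
              x$selected_C,
              x$nonzero_features[which(x$c_grid == x$selected_C)[1]],
              if (length(x$selected_features))
                paste0(": ", paste(x$selected_features, collapse = ", ")) else ""))
  if (!is.null(x$p_permutation)) cat(sprintf("  permutation p = %.4g\n", x$p_permutation))
  invisible(x)
}

#' Optimal inverse regularization strength
#'
#' Among C values whose mean balanced accuracy is within `tol` of the
#' maximum, selects the one with the fewest non-zero coefficients, breaking
#' remaining ties by the smaller C.
#'
#' @param cv `lasso_cv_result`.
#' @param tol tie tolerance on balanced accuracy (default 1e-4).
#' @return selected C (scalar).
#' @export
select_optimal_C <- function(cv, tol = 1e-4) {
  ba <- cv$balanced_accuracy_mean
  cand <- which(ba >= max(ba) - tol)
  cand <- cand[order(cv$nonzero_features[cand], cv$c_grid[cand])]
  cv$c_grid[cand[1]]
}

#' Permutation significance of the cross-validated balanced accuracy
#'
#' Repeats the cross-validation on label-permuted data and reports the
#' smoothed two-sided probability of a mean balanced accuracy at least as far
#' from 0.5 as observed. For tractability each permutation is evaluated at
#' the observed run's selected C (the statistic is |BA - 0.5| at that C).
#'
#' @param features,labels as in [lasso_cv()].
#' @param k,seed as in [lasso_cv()].
#' @param c_value C at which to evaluate; default: selected C of the
#'   observed run.
#' @param n_perm permutations (default 10000; < 100 warns).
#' @return list(p, observed_ba, null_ba).
#' @export
permutation_significance <- function(features, labels, k = 5, c_value = NULL,
                                     n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: permutation p-value is coarse")
  x <- as.matrix(features); y <- as.integer(labels)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  if (is.null(c_value)) {
    cv <- lasso_cv(x, y, k = k, n_c = 50, seed = seed)
    c_value <- cv$selected_C
  }
  ba_at <- function(yy) {
    cv1 <- lasso_cv(x, yy, k = k, c_grid = c_value, seed = sample.int(2^30, 1))
    cv1$balanced_accuracy_mean[1]
  }
  obs <- ba_at(y)
  null <- vapply(seq_len(n_perm), function(t) ba_at(sample(y)), 0)
  p <- (sum(abs(null - 0.5) >= abs(obs - 0.5) - 1e-12) + 1) / (n_perm + 1)
  list(p = p, observed_ba = obs, null_ba = null)
}
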