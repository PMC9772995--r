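#' Configuration of the repeated cross-validated regression
#'
#' @param k number of folds (default 5).
#' @param repetitions number of independent CV repetitions (default 100).
#' @param trees random-forest size per fold model (default 500).
#' @param mtry features tried per split; default `floor(F/3)`, minimum 1,
#'   where `F` is the number of input features.
#' @param permutations permutations for the R-squared permutation test
#'   (default 1000; 0 disables the test and reports an NA p-value).
#' @param alpha significance level before Bonferroni correction across
#'   years (default 0.01).
#' @param dispersion "sd" (standard deviation across repetitions, the
#'   default) or "sem" (standard error of the mean).
#' @param null_repetitions CV repetitions per permutation in the null
#'   distribution (default 1; the observed statistic always uses
#'   `repetitions`).
#' @param seed integer seed (NULL: current RNG stream).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k = 5L, repetitions = 100L, trees = 500L, mtry = NULL,
                      permutations = 1000L, alpha = 0.01,
                      dispersion = c("sd", "sem"), null_repetitions = 1L,
                      seed = NULL) {
  k <- check_count(k, "k", min = 2L)
  repetitions <- check_count(repetitions, "repetitions")
  trees <- check_count(trees, "trees")
  if (!is.null(mtry)) mtry <- check_count(mtry, "mtry")
  permutations <- check_count(permutations, "permutations", min = 0L)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1,
                        strict_min = TRUE, strict_max = TRUE)
  null_repetitions <- check_count(null_repetitions, "null_repetitions")
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(list(k = k, repetitions = repetitions, trees = trees, mtry = mtry,
                 permutations = permutations, alpha = alpha,
                 dispersion = match.arg(dispersion),
                 null_repetitions = null_repetitions, seed = seed),
            class = "cv_config")
}

#' Root mean square error
#' @param actual,forecast numeric vectors of equal length.
#' @return `sqrt(mean((actual - forecast)^2))`.
#' @export
rmse <- function(actual, forecast) {
  if (length(actual) != length(forecast)) stop("length mismatch")
  if (length(actual) == 0L) stop("empty vectors")
  sqrt(mean((actual - forecast)^2))
}

#' Mean absolute percentage error
#'
#' `mean(|actual - forecast| / |actual|)`. A zero actual value makes the
#' ratio undefined; the target here (prevalence per 100,000) is strictly
#' positive, so a zero flags corrupted input and raises an error.
#'
#' @param actual,forecast numeric vectors of equal length.
#' @return the MAPE as a fraction (0.10 = 10%).
#' @export
mape <- function(actual, forecast) {
  if (length(actual) != length(forecast)) stop("length mismatch")
  if (any(actual == 0)) stop("actual values must be nonzero for MAPE")
  mean(abs((actual - forecast) / actual))
}

#' Coefficient of determination
#' @param actual,forecast numeric vectors of equal length; `actual` must
#'   not be constant.
#' @return `1 - SS_res / SS_tot`.
#' @export
r2_score <- function(actual, forecast) {
  if (length(actual) != length(forecast)) stop("length mismatch")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) stop("actual values are constant; R-squared undefined")
  1 - sum((actual - forecast)^2) / ss_tot
}

rf_mtry <- function(config, p) {
  if (!is.null(config$mtry)) min(config$mtry, p) else max(1L, floor(p / 3))
}

fit_rf <- function(X, y, config, seed, importance = "impurity") {
  ranger::ranger(
    x = X, y = y, num.trees = config$trees, mtry = rf_mtry(config, ncol(X)),
    importance = importance,
    seed = if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
    num.threads = 1L)
}

#' Repeated k-fold cross-validated random-forest predictions
#'
#' For each repetition a fresh seeded k-fold partition is drawn, one
#' forest is trained per fold on the remaining folds, and predictions are
#' collected on the held-out fold, so each sample has exactly one
#' out-of-fold prediction per repetition. Mean-decrease-impurity
#' importances of the fold models are normalized to sum to 1 per model
#' and averaged over the k folds within each repetition.
#'
#' @param X numeric matrix (samples x features), complete.
#' @param y numeric target vector.
#' @param config a [cv_config()].
#' @param collect_models logical; also return the fitted fold models and
#'   fold assignments (used by the Shapley aggregation).
#' @return list with `oof` (n x repetitions matrix of out-of-fold
#'   predictions), `importance` (features x repetitions matrix), `folds`
#'   (n x repetitions fold ids) and, if requested, `models` (list of
#'   lists of ranger fits).
#' @export
repeated_cv <- function(X, y, config = cv_config(), collect_models = FALSE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X)
  if (n < 2L * config$k) {
    stop(sprintf("need at least %d samples for %d folds; use fewer folds",
                 2L * config$k, config$k))
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  reps <- config$repetitions
  oof <- matrix(NA_real_, n, reps)
  folds <- matrix(NA_integer_, n, reps)
  imp <- matrix(0, ncol(X), reps, dimnames = list(colnames(X), NULL))
  models <- if (collect_models) vector("list", reps) else NULL

  for (r in seq_len(reps)) {
    fold_id <- with_seed(derive_seed(config$seed, 2L, r),
                         sample(rep(seq_len(config$k), length.out = n)))
    folds[, r] <- fold_id
    rep_models <- if (collect_models) vector("list", config$k) else NULL
    for (f in seq_len(config$k)) {
      test <- fold_id == f
      fit <- fit_rf(X[!test, , drop = FALSE], y[!test], config,
                    seed = derive_seed(config$seed, 3L, r, f))
      oof[test, r] <- stats::predict(
        fit, data = X[test, , drop = FALSE], num.threads = 1L)$predictions
      vi <- fit$variable.importance
      s <- sum(vi)
      imp[, r] <- imp[, r] + (if (s > 0) vi / s else vi) / config$k
      if (collect_models) rep_models[[f]] <- fit
    }
    if (collect_models) models[[r]] <- rep_models
  }
  out <- list(oof = oof, importance = imp, folds = folds)
  if (collect_models) out$models <- models
  out
}

disperse <- function(x, kind) {
  if (kind == "sd") stats::sd(x) else stats::sd(x) / sqrt(length(x))
}

#' Per-year regression performance report
#'
#' Runs [repeated_cv()] and summarizes, across repetitions, the pooled
#' out-of-fold R-squared, RMSE and MAPE (mean and dispersion), the
#' CV-averaged mean-decrease-impurity feature importance, the mean
#' out-of-fold prediction per sample, and (when `config$permutations > 0`)
#' the permutation p-value of the mean R-squared.
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric target vector (strictly positive for MAPE).
#' @param config a [cv_config()].
#' @param year optional year label.
#' @return object of class `regression_report`.
#' @export
regression_report <- function(X, y, config = cv_config(), year = NA_integer_) {
  cv <- repeated_cv(X, y, config)
  r2s <- apply(cv$oof, 2, r2_score, actual = y)
  rmses <- apply(cv$oof, 2, rmse, actual = y)
  mapes <- apply(cv$oof, 2, mape, actual = y)
  d <- config$dispersion
  p_value <- if (config$permutations > 0) {
    r2_permutation_pvalue(X, y, config, observed = mean(r2s))
  } else NA_real_
  structure(list(
    year = year,
    n = length(y),
    features = rownames(cv$importance),
    r2 = c(mean = mean(r2s), dispersion = disperse(r2s, d)),
    rmse = c(mean = mean(rmses), dispersion = disperse(rmses, d)),
    mape = c(mean = mean(mapes), dispersion = disperse(mapes, d)),
    p_value = p_value,
    importance = data.frame(
      indicator = rownames(cv$importance),
      mean = rowMeans(cv$importance),
      dispersion = apply(cv$importance, 1, disperse, kind = d),
      stringsAsFactors = FALSE, row.names = NULL),
    oof_predictions = stats::setNames(rowMeans(cv$oof), rownames(X)),
    repetitions = config$repetitions
  ), class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("regression_report%s: n = %d, %d features, %d repetitions\n",
              if (is.na(x$year)) "" else sprintf(" [year %d]", x$year),
              x$n, length(x$features), x$repetitions))
  cat(sprintf("  R2   %.3f +/- %.3f\n  RMSE %.3f +/- %.3f\n  MAPE %.3f +/- %.3f\n",
              x$r2[1], x$r2[2], x$rmse[1], x$rmse[2], x$mape[1], x$mape[2]))
  if (!is.na(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' Permutation p-value for the cross-validated R-squared
#'
#' The target is permuted before each null CV run and the empirical
#' p-value is `(1 + #{null mean R2 >= observed}) / (1 + permutations)`.
#' Null runs use `config$null_repetitions` CV repetitions each (default
#' 1); the observed statistic uses the full `config$repetitions`.
#'
#' @param X numeric matrix.
#' @param y numeric target.
#' @param config a [cv_config()] with `permutations >= 19`.
#' @param observed optional precomputed observed mean R-squared.
#' @return the p-value in `(0, 1]`.
#' @export
r2_permutation_pvalue <- function(X, y, config = cv_config(), observed = NULL) {
  if (config$permutations < 19L) {
    stop("need at least 19 permutations for usable p-value resolution")
  }
  if (is.null(observed)) {
    cv <- repeated_cv(X, y, config)
    observed <- mean(apply(cv$oof, 2, r2_score, actual = y))
  }
  null_cfg <- config
  null_cfg$repetitions <- config$null_repetitions
  exceed <- 0L
  for (b in seq_len(config$permutations)) {
    y_perm <- with_seed(derive_seed(config$seed, 4L, b), sample(y))
    null_cfg$seed <- derive_seed(config$seed, 5L, b)
    cvb <- repeated_cv(X, y_perm, null_cfg)
    r2b <- mean(apply(cvb$oof, 2, r2_score, actual = y_perm))
    if (r2b >= observed) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + config$permutations)
}

#' CV-averaged feature importance
#'
#' Mean-decrease-impurity importance extracted from every fold model,
#' normalized per model, averaged within repetition, then summarized as
#' mean and dispersion across repetitions.
#'
#' @inheritParams regression_report
#' @return data.frame `indicator,mean,dispersion`.
#' @export
importance_over_cv <- function(X, y, config = cv_config()) {
  cv <- repeated_cv(X, y, config)
  data.frame(indicator = rownames(cv$importance),
             mean = rowMeans(cv$importance),
             dispersion = apply(cv$importance, 1, disperse,
                                kind = config$dispersion),
             stringsAsFactors = FALSE, row.names = NULL)
}
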