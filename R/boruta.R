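#' Configuration of the shadow-feature selector
#'
#' @param n_iterations number of independent shadow-shuffle iterations
#'   (default 100; at least 10 so the binomial hit test has resolution).
#' @param alpha significance level of the hit test (default 0.05).
#' @param multiple_testing "bonferroni" (default) or "holm", applied
#'   across candidate features.
#' @param importance "impurity" (mean decrease impurity, the default, so
#'   selection and the downstream regression use the same measure) or
#'   "permutation".
#' @param trees random-forest size per iteration (default 500).
#' @param mtry features tried per split; default `floor(p/3)` of the
#'   shadow-extended matrix, minimum 1.
#' @param seed integer seed (NULL: current RNG stream).
#' @return object of class `boruta_config`.
#' @export
boruta_config <- function(n_iterations = 100L, alpha = 0.05,
                          multiple_testing = c("bonferroni", "holm"),
                          importance = c("impurity", "permutation"),
                          trees = 500L, mtry = NULL, seed = NULL) {
  n_iterations <- check_count(n_iterations, "n_iterations", min = 10L)
  alpha <- check_number(alpha, "alpha", min = 0, max = 1,
                        strict_min = TRUE, strict_max = TRUE)
  trees <- check_count(trees, "trees")
  if (!is.null(mtry)) mtry <- check_count(mtry, "mtry")
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_iterations = n_iterations, alpha = alpha,
                 multiple_testing = match.arg(multiple_testing),
                 importance = match.arg(importance),
                 trees = trees, mtry = mtry, seed = seed),
            class = "boruta_config")
}

#' Append shadow features to a design matrix
#'
#' Each shadow column is an independent row-permutation of its original
#' column, destroying any association with the target while preserving
#' the marginal distribution. Shadow columns are named
#' `shadow_<original>`.
#'
#' @param X numeric matrix with at least 2 rows and named columns.
#' @param seed integer seed (NULL: current RNG stream).
#' @return matrix with `2 * ncol(X)` columns, originals first.
#' @export
make_shadows <- function(X, seed = NULL) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 2L) stop("shuffling is undefined for a single-row matrix")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  with_seed(seed, {
    shadows <- apply(X, 2, sample)
    colnames(shadows) <- paste0("shadow_", colnames(X))
    cbind(X, shadows)
  })
}

#' Shadow-feature (Boruta-style) all-relevant selection
#'
#' At every iteration the design matrix is extended with freshly shuffled
#' shadow copies of all features and a random forest is fit on the
#' extension; a feature scores a hit when its importance strictly exceeds
#' the maximum shadow importance of that iteration (ties count as no
#' hit). After `n_iterations` iterations, one-sided binomial tests
#' (success probability 0.5, corrected for multiple testing across
#' features) classify each feature as selected (significantly more hits
#' than chance), rejected (significantly fewer), or tentative. Tentative
#' features are resolved by comparing their median importance over
#' iterations with the median of the per-iteration maximum shadow
#' importances.
#'
#' @param X numeric matrix (countries x features), no missing values.
#' @param y numeric target vector aligned with the rows of `X`.
#' @param config a [boruta_config()].
#' @param year optional year label carried into the result.
#' @return object of class `boruta_result`: `selected`, `rejected`
#'   (partitioning the candidates after tentative resolution),
#'   `tentative` (the features that needed resolution), `importance`
#'   (mean importance per candidate over iterations), `hit_counts`,
#'   `n_iterations`, `year`.
#' @export
boruta_select <- function(X, y, config = boruta_config(), year = NA_integer_) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 10L) stop("need at least 10 rows for the hit test to be meaningful")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  feats <- colnames(X)
  p <- length(feats)
  n_it <- config$n_iterations

  imp_mat <- matrix(NA_real_, n_it, p, dimnames = list(NULL, feats))
  max_shadow <- numeric(n_it)
  for (it in seq_len(n_it)) {
    it_seed <- derive_seed(config$seed, 1L, it)
    ext <- make_shadows(X, seed = it_seed)
    mtry <- if (is.null(config$mtry)) max(1L, floor(ncol(ext) / 3)) else config$mtry
    fit <- ranger::ranger(
      x = ext, y = y, num.trees = config$trees, mtry = mtry,
      importance = config$importance,
      seed = if (is.null(it_seed)) sample.int(.Machine$integer.max, 1) else it_seed,
      num.threads = 1L
    )
    imp <- fit$variable.importance
    imp_mat[it, ] <- imp[feats]
    max_shadow[it] <- max(imp[paste0("shadow_", feats)])
  }

  hits <- colSums(imp_mat > max_shadow)
  p_sel <- stats::pbinom(hits - 1L, n_it, 0.5, lower.tail = FALSE)
  p_rej <- stats::pbinom(hits, n_it, 0.5)
  p_sel <- stats::p.adjust(p_sel, method = config$multiple_testing)
  p_rej <- stats::p.adjust(p_rej, method = config$multiple_testing)

  selected <- feats[p_sel < config$alpha]
  rejected <- feats[p_rej < config$alpha & p_sel >= config$alpha]
  tentative <- setdiff(feats, c(selected, rejected))
  if (length(tentative)) {
    med_shadow <- stats::median(max_shadow)
    promote <- apply(imp_mat[, tentative, drop = FALSE], 2, stats::median) > med_shadow
    selected <- c(selected, tentative[promote])
    rejected <- c(rejected, tentative[!promote])
  }
  if (length(selected) == 0L) {
    warning(sprintf("no feature selected%s; downstream callers fall back to the full set",
                    if (is.na(year)) "" else sprintf(" for year %d", year)))
  }

  structure(list(
    year = year,
    selected = selected, rejected = rejected, tentative = tentative,
    importance = colMeans(imp_mat),
    hit_counts = stats::setNames(as.integer(hits), feats),
    n_iterations = n_it
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("boruta_result%s: %d selected / %d rejected (%d were tentative) of %d candidates, %d iterations\n",
              if (is.na(x$year)) "" else sprintf(" [year %d]", x$year),
              length(x$selected), length(x$rejected), length(x$tentative),
              length(x$importance), x$n_iterations))
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-year importance table from selection results
#'
#' Stacks the mean importances of one or more [boruta_select()] results
#' into the long table that feeds the competition network and the
#' importance heat-map export.
#'
#' @param results a `boruta_result` or list of them (one per year).
#' @return data.frame `year,indicator,importance,selected`.
#' @export
importance_table <- function(results) {
  if (inherits(results, "boruta_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(year = r$year, indicator = names(r$importance),
               importance = unname(r$importance),
               selected = names(r$importance) %in% r$selected,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
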