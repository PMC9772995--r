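# subset masks for |S| = p features: 2^p x p logical matrix, row order
# by bitmask value so subset F and F + {j} are related by bit arithmetic.
subset_masks <- function(p) {
  masks <- matrix(FALSE, 2^p, p)
  for (j in seq_len(p)) {
    masks[, j] <- bitwAnd(0:(2^p - 1), bitwShiftL(1L, j - 1L)) > 0L
  }
  masks
}

# Shapley kernel weight for adding one feature to a subset of size s
# out of p features: s! (p - s - 1)! / p!
shapley_weights <- function(p) {
  s <- 0:(p - 1)
  exp(lgamma(s + 1) + lgamma(p - s) - lgamma(p + 1))
}

#' Ordinary-least-squares trainer for Shapley retraining
#'
#' A deterministic trainer: fits an intercept-plus-linear model on the
#' given columns and returns a prediction function. With zero columns it
#' predicts the training-target mean.
#'
#' @param X numeric matrix (possibly with zero columns).
#' @param y numeric target.
#' @return function mapping a matrix with the same columns to predictions.
#' @export
linear_trainer <- function(X, y) {
  if (ncol(X) == 0L) {
    mu <- mean(y)
    return(function(newX) rep(mu, nrow(newX)))
  }
  fit <- stats::lm.fit(cbind(1, X), y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  function(newX) drop(cbind(1, newX) %*% beta)
}

#' Exact Shapley values by retraining on every feature subset
#'
#' The literal game-theoretic attribution: for every subset F of the
#' feature set S, a model is trained on the columns in F and evaluated at
#' the instance restricted to F; the Shapley value of feature j combines
#' the marginal contributions f_x(F + j) - f_x(F) with the weights
#' |F|! (|S| - |F| - 1)! / |S|!. The empty-set value is the training
#' target mean. Exponential in the number of features, so capped at 12;
#' use [shapley_marginal_estimate()] beyond that.
#'
#' @param x numeric instance (named like the columns of `X`).
#' @param X numeric training matrix.
#' @param y numeric training target.
#' @param trainer function `(X_sub, y) -> prediction function`; must be
#'   deterministic for the Shapley axioms to hold exactly (default
#'   [linear_trainer()]).
#' @return named numeric vector of Shapley values, with attribute
#'   `"baseline"` = mean of `y`.
#' @export
exact_shapley_retrain <- function(x, X, y, trainer = linear_trainer) {
  stopifnot(is.matrix(X), length(x) == ncol(X), nrow(X) == length(y))
  p <- ncol(X)
  if (p > 12L) {
    stop("more than 12 features: 2^p retrainings are infeasible; use shapley_marginal_estimate()")
  }
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(p))
  masks <- subset_masks(p)
  v <- numeric(nrow(masks))
  xm <- matrix(x, nrow = 1, dimnames = list(NULL, colnames(X)))
  for (m in seq_len(nrow(masks))) {
    F_idx <- which(masks[m, ])
    if (length(F_idx) == 0L) {
      v[m] <- mean(y)
    } else {
      model <- trainer(X[, F_idx, drop = FALSE], y)
      v[m] <- model(xm[, F_idx, drop = FALSE])
    }
  }
  combine_subset_values(v, masks, p, colnames(X))
}

# fold subset values v (length 2^p, bitmask order) into Shapley values
combine_subset_values <- function(v, masks, p, feat_names) {
  w <- shapley_weights(p)
  sizes <- rowSums(masks)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(!masks[, j])
    with_j <- without + bit   # mask index is bitmask + 1
    phi[j] <- sum(w[sizes[without] + 1L] * (v[with_j] - v[without]))
  }
  structure(stats::setNames(phi, feat_names), baseline = v[1])
}

as_predict_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "ranger")) {
    return(function(m) stats::predict(model, data = m,
                                      num.threads = 1L)$predictions)
  }
  function(m) as.numeric(stats::predict(model, as.data.frame(m)))
}

# Exact marginal (interventional) Shapley values for a batch of query
# rows against one trained model: v(F) is the model output averaged over
# background rows with the features in F replaced by the query's values.
# One batched prediction call over all subsets x queries x background.
marginal_exact_batch <- function(predict_fun, Xq, background) {
  p <- ncol(Xq)
  nq <- nrow(Xq)
  nb <- nrow(background)
  masks <- subset_masks(p)
  nm <- nrow(masks)
  big <- matrix(NA_real_, nm * nq * nb, p, dimnames = list(NULL, colnames(Xq)))
  row0 <- 0L
  for (m in seq_len(nm)) {
    F_idx <- which(masks[m, ])
    for (q in seq_len(nq)) {
      Z <- background
      if (length(F_idx)) {
        Z[, F_idx] <- matrix(Xq[q, F_idx], nb, length(F_idx), byrow = TRUE)
      }
      big[row0 + seq_len(nb), ] <- Z
      row0 <- row0 + nb
    }
  }
  preds <- predict_fun(big)
  grp <- rep(seq_len(nm * nq), each = nb)
  v <- matrix(rowsum(preds, grp) / nb, nrow = nm, ncol = nq, byrow = TRUE)
  phi <- matrix(NA_real_, nq, p, dimnames = list(rownames(Xq), colnames(Xq)))
  for (q in seq_len(nq)) {
    sv <- combine_subset_values(v[, q], masks, p, colnames(Xq))
    phi[q, ] <- sv
  }
  list(phi = phi, baseline = v[1, 1])
}

# Permutation-sampling marginal Shapley values for one query row:
# each draw pairs a random feature order with a random background row
# and walks the chain from background to query, crediting each feature
# with its prediction change. Unbiased for the marginal value function.
marginal_sampled <- function(predict_fun, x, background, n_samples, seed) {
  p <- length(x)
  nb <- nrow(background)
  with_seed(seed, {
    perms <- replicate(n_samples, sample.int(p), simplify = FALSE)
    b_idx <- sample.int(nb, n_samples, replace = TRUE)
    big <- matrix(NA_real_, n_samples * (p + 1L), p,
                  dimnames = list(NULL, names(x)))
    for (s in seq_len(n_samples)) {
      z <- background[b_idx[s], ]
      base_row <- (s - 1L) * (p + 1L)
      big[base_row + 1L, ] <- z
      for (step in seq_len(p)) {
        z[perms[[s]][step]] <- x[perms[[s]][step]]
        big[base_row + 1L + step, ] <- z
      }
    }
    preds <- predict_fun(big)
    phi <- numeric(p)
    for (s in seq_len(n_samples)) {
      base_row <- (s - 1L) * (p + 1L)
      deltas <- diff(preds[base_row + seq_len(p + 1L)])
      phi[perms[[s]]] <- phi[perms[[s]]] + deltas
    }
    stats::setNames(phi / n_samples, names(x))
  })
}

#' Model-agnostic Shapley values under the marginal value function
#'
#' Approximates the subset value f_x(F) by averaging the model output
#' over background rows whose features outside F are kept and whose
#' features in F are replaced by the instance's values (marginal /
#' interventional value function). `exact_subsets` mode enumerates all
#' 2^p subsets (p <= 15); `sampled` mode averages marginal contributions
#' over random feature permutations paired with random background rows.
#'
#' @param model a fitted model (`ranger` fit, anything with a `predict`
#'   method, or a prediction function taking a matrix).
#' @param x numeric instance, named like the background columns.
#' @param background numeric matrix of reference rows (non-empty).
#' @param mode "exact_subsets" or "sampled".
#' @param n_samples number of permutations in sampled mode (at least p).
#' @param seed integer seed for sampled mode.
#' @return named numeric vector of Shapley values; attribute
#'   `"baseline"` = mean model output over the background (exact mode).
#' @export
shapley_marginal_estimate <- function(model, x, background,
                                      mode = c("exact_subsets", "sampled"),
                                      n_samples = 2000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(background), nrow(background) >= 1L,
            length(x) == ncol(background))
  predict_fun <- as_predict_fun(model)
  if (is.null(names(x))) names(x) <- colnames(background)
  p <- length(x)
  if (mode == "exact_subsets") {
    if (p > 15L) stop("more than 15 features: use sampled mode")
    res <- marginal_exact_batch(predict_fun,
                                matrix(x, 1, dimnames = list(NULL, names(x))),
                                background)
    structure(stats::setNames(drop(res$phi), names(x)), baseline = res$baseline)
  } else {
    if (n_samples < p) stop("n_samples must be at least the number of features")
    phi <- marginal_sampled(predict_fun, x, background, n_samples, seed)
    structure(phi, baseline = mean(predict_fun(background)))
  }
}

#' Per-country Shapley values aggregated over repeated cross-validation
#'
#' Reproduces the CV scheme of [repeated_cv()] (same seeded fold
#' partitions and fold-model seeds): in each repetition every country is
#' held out exactly once, its Shapley vector is computed from the model
#' of the fold that held it out, with (a subsample of) that model's
#' training fold as background; the final matrix is the mean over
#' repetitions.
#'
#' @param X numeric matrix (countries x features), complete, with
#'   rownames.
#' @param y numeric target vector.
#' @param config a [cv_config()].
#' @param year optional year label.
#' @param mode "exact_subsets" (default; feature count capped at 15) or
#'   "sampled".
#' @param background_size background rows drawn from the training fold
#'   (default 50).
#' @param n_samples permutations per country in sampled mode.
#' @return object of class `shap_matrix`: `year`, `countries`,
#'   `features`, `values` (countries x features), `baseline` (mean
#'   background model output over folds and repetitions).
#' @export
shap_over_cv <- function(X, y, config = cv_config(), year = NA_integer_,
                         mode = c("exact_subsets", "sampled"),
                         background_size = 50L, n_samples = 2000L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(rownames(X))) rownames(X) <- sprintf("r%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (mode == "exact_subsets" && p > 15L) {
    stop("more than 15 features: use sampled mode")
  }
  reps <- config$repetitions
  acc <- matrix(0, n, p, dimnames = list(rownames(X), colnames(X)))
  baseline_acc <- 0
  for (r in seq_len(reps)) {
    fold_id <- with_seed(derive_seed(config$seed, 2L, r),
                         sample(rep(seq_len(config$k), length.out = n)))
    for (f in seq_len(config$k)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      fit <- fit_rf(X[train, , drop = FALSE], y[train], config,
                    seed = derive_seed(config$seed, 3L, r, f))
      bg_idx <- if (length(train) > background_size) {
        with_seed(derive_seed(config$seed, 6L, r, f),
                  sample(train, background_size))
      } else train
      bg <- X[bg_idx, , drop = FALSE]
      pf <- as_predict_fun(fit)
      if (mode == "exact_subsets") {
        res <- marginal_exact_batch(pf, X[test, , drop = FALSE], bg)
        acc[test, ] <- acc[test, ] + res$phi
        baseline_acc <- baseline_acc + res$baseline / config$k
      } else {
        for (i in test) {
          acc[i, ] <- acc[i, ] + marginal_sampled(
            pf, X[i, ], bg, n_samples, derive_seed(config$seed, 7L, r, f, i))
        }
        baseline_acc <- baseline_acc + mean(pf(bg)) / config$k
      }
    }
  }
  structure(list(year = year, countries = rownames(X), features = colnames(X),
                 values = acc / reps, baseline = baseline_acc / reps),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("shap_matrix%s: %d countries x %d features, baseline %.3f\n",
              if (is.na(x$year)) "" else sprintf(" [year %d]", x$year),
              length(x$countries), length(x$features), x$baseline))
  ma <- sort(colMeans(abs(x$values)), decreasing = TRUE)
  cat("  mean |SHAP|:", paste(sprintf("%s=%.2f", names(ma), ma), collapse = ", "), "\n")
  invisible(x)
}

#' Retain features by the 25%-of-total mean-absolute-SHAP rule
#'
#' Three steps: (1) the impact of each feature is its mean absolute
#' Shapley value over countries; (2) the total is the sum of those
#' impacts over features; (3) a feature is retained when its impact is
#' strictly larger than `threshold` of the total. With the default 0.25
#' threshold at most three features can ever be retained.
#'
#' @param shap a [shap_over_cv()] result (or any `shap_matrix`).
#' @param threshold retention fraction of the total (default 0.25).
#' @return object of class `retained_features`: `year`, `mean_abs`,
#'   `total`, `retained`.
#' @export
retain_features <- function(shap, threshold = 0.25) {
  stopifnot(inherits(shap, "shap_matrix"))
  threshold <- check_number(threshold, "threshold", min = 0, max = 1)
  mean_abs <- colMeans(abs(shap$values))
  total <- sum(mean_abs)
  structure(list(year = shap$year, mean_abs = mean_abs, total = total,
                 retained = names(mean_abs)[mean_abs > threshold * total]),
            class = "retained_features")
}

#' Tidy per-country SHAP export
#'
#' @param shap a `shap_matrix`.
#' @param X optional feature-value matrix aligned with the SHAP matrix,
#'   to include the underlying feature values (beeswarm-style export).
#' @return data.frame `feature,country,shap[,feature_value]`.
#' @export
shap_long <- function(shap, X = NULL) {
  stopifnot(inherits(shap, "shap_matrix"))
  out <- data.frame(
    feature = rep(shap$features, each = length(shap$countries)),
    country = rep(shap$countries, times = length(shap$features)),
    shap = as.vector(shap$values),
    stringsAsFactors = FALSE)
  if (!is.null(X)) {
    out$feature_value <- as.vector(X[shap$countries, shap$features])
  }
  out
}
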