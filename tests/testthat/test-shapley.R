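test_that("exact retraining Shapley satisfies efficiency, dummy and symmetry", {
  with_seed_test(21, {
    n <- 30
    # columns orthonormal and orthogonal to the intercept, so inactive
    # features are exact dummies under OLS
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 5), n, 5))))[, -1]
    colnames(Q) <- paste0("f", 1:5)
    beta <- c(3, -2, 0, 0, 0)
    y <- drop(Q %*% beta)                  # noiseless, f3..f5 ignored
    x <- Q[7, ]
    phi <- exact_shapley_retrain(x, Q, y)
    full <- linear_trainer(Q, y)(matrix(x, 1))
    expect_lt(abs(sum(phi) - (full - mean(y))), 1e-8)       # efficiency
    expect_lt(max(abs(phi[3:5])), 1e-8)                      # dummy
    # symmetry: identical columns, equal instance coordinates
    Xs <- cbind(a = Q[, 1], b = Q[, 1], c = Q[, 2])
    ys <- drop(Q[, 1:2] %*% c(2, 1))
    xs <- Xs[3, ]
    phis <- exact_shapley_retrain(xs, Xs, ys)
    expect_lt(abs(phis["a"] - phis["b"]), 1e-8)
  })
})

test_that("the retraining oracle errors out beyond 12 features", {
  X <- matrix(rnorm(20 * 13), 20, 13)
  expect_error(exact_shapley_retrain(X[1, ], X, rnorm(20)),
               "shapley_marginal_estimate")
})

test_that("marginal Shapley of a linear model matches the closed form", {
  with_seed_test(22, {
    p <- 6
    beta <- rnorm(p)
    bg <- matrix(rnorm(40 * p), 40, p, dimnames = list(NULL, paste0("f", 1:p)))
    x <- rnorm(p); names(x) <- paste0("f", 1:p)
    model <- linear_model_fun(beta, intercept = 5)
    phi <- shapley_marginal_estimate(model, x, bg, mode = "exact_subsets")
    expect_equal(as.vector(phi), unname(beta * (x - colMeans(bg))),
                 tolerance = 1e-6)
    # efficiency for the marginal value function
    expect_equal(sum(phi), model(matrix(x, 1)) - mean(model(bg)),
                 tolerance = 1e-10)
    expect_equal(attr(phi, "baseline"), mean(model(bg)))
    # sampled mode converges to the same values
    phi_s <- shapley_marginal_estimate(model, x, bg, mode = "sampled",
                                       n_samples = 4000, seed = 9)
    rng <- diff(range(c(model(bg), model(matrix(x, 1)))))
    expect_lt(max(abs(phi_s - phi)), 0.02 * rng)
    expect_error(shapley_marginal_estimate(model, x, bg, mode = "sampled",
                                           n_samples = 3), "n_samples")
  })
})

test_that("marginal and retraining Shapley agree on a deterministic toy", {
  with_seed_test(23, {
    n <- 60; p <- 6
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- drop(X %*% c(3, -2, 1, 0, 0, 0))
    x <- X[11, ]
    phi_rt <- exact_shapley_retrain(x, X, y)
    model <- linear_trainer(X, y)
    phi_mg <- shapley_marginal_estimate(model, x, X, mode = "exact_subsets")
    # different value functions, but close on a well-posed linear problem
    expect_lt(max(abs(phi_rt - phi_mg)), 0.05 * diff(range(y)))
  })
})

test_that("CV-aggregated Shapley is deterministic and finds the driving feature", {
  d <- signal_matrix(n = 60, p = 4, support = 1, beta = 4, r2_true = 0.97,
                     seed = 24)
  cfg <- cv_config(repetitions = 3, trees = 100, permutations = 0, seed = 25)
  sm <- shap_over_cv(d$X, d$y, cfg, year = 2003, background_size = 20)
  expect_s3_class(sm, "shap_matrix")
  expect_equal(dim(sm$values), c(60, 4))
  expect_setequal(sm$features, colnames(d$X))
  expect_true(all(is.finite(sm$values)))
  # the informative feature dominates the attribution: largest for most
  # countries and several-fold larger on average than any noise feature
  dom <- apply(abs(sm$values), 1, which.max)
  expect_gt(mean(dom == 1), 0.8)
  ma <- colMeans(abs(sm$values))
  expect_gt(ma["f01"], 3 * max(ma[-1]))
  sm2 <- shap_over_cv(d$X, d$y, cfg, year = 2003, background_size = 20)
  expect_identical(sm$values, sm2$values)
})

test_that("the 25% retention rule follows the three steps with a strict threshold", {
  mk <- function(mean_abs) {
    # single-country SHAP matrix whose |values| equal mean_abs exactly
    structure(list(year = 2000L, countries = "C1", features = names(mean_abs),
                   values = matrix(mean_abs, 1,
                                   dimnames = list("C1", names(mean_abs))),
                   baseline = 0), class = "shap_matrix")
  }
  r <- retain_features(mk(c(a = 0.6, b = 0.3, c = 0.1)))
  expect_equal(r$total, 1.0)
  expect_setequal(r$retained, c("a", "b"))
  expect_setequal(retain_features(mk(c(a = 0.25, b = 0.75)))$retained, "b")
  expect_length(retain_features(mk(c(a = .25, b = .25, c = .25, d = .25)))$retained, 0)
  r0 <- retain_features(mk(c(a = 0, b = 0)))
  expect_equal(r0$total, 0)
  expect_length(r0$retained, 0)
})

test_that("tidy SHAP export carries values and feature values", {
  d <- signal_matrix(n = 40, p = 3, support = 1, beta = 2, r2_true = 0.9,
                     seed = 26)
  cfg <- cv_config(repetitions = 1, trees = 50, permutations = 0, seed = 27)
  sm <- shap_over_cv(d$X, d$y, cfg, background_size = 15)
  tidy <- shap_long(sm, d$X)
  expect_equal(nrow(tidy), 40 * 3)
  expect_named(tidy, c("feature", "country", "shap", "feature_value"))
  i <- which(tidy$feature == "f02" & tidy$country == rownames(d$X)[5])
  expect_equal(tidy$shap[i], sm$values[5, "f02"])
  expect_equal(tidy$feature_value[i], d$X[5, "f02"])
})
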