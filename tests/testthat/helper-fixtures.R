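# Small in-code fixtures shared across test files.

# tiny panel: 8 countries x 4 years x 3 indicators, complete
tiny_panel <- function(seed = 1, missing_rate = 0) {
  generate_panel(panel_config(
    n_countries = 8, years = 2001:2004, n_indicators = 3, support_size = 1,
    effect_sizes = 50, noise_sd = 10, missing_rate = missing_rate,
    availability_windows = stats::setNames(rep(list(2001:2004), 3),
                                           sprintf("ind_%02d", 1:3)),
    trend_degree = 1, seed = seed))
}

# design matrix + target with known linear signal and chosen true R2
signal_matrix <- function(n, p, support, beta, r2_true, seed) {
  stopifnot(length(beta) == support, support <= p)
  with_seed_test(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(sprintf("r%03d", 1:n), sprintf("f%02d", 1:p)))
    sig <- drop(X[, seq_len(support), drop = FALSE] %*% beta)
    noise_sd <- sqrt(stats::var(sig) * (1 - r2_true) / r2_true)
    list(X = X, y = sig + stats::rnorm(n, 0, noise_sd),
         signal = sig, noise_sd = noise_sd)
  })
}

# seed-scoped evaluation without touching the suite's RNG stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# linear prediction closure for a known coefficient vector (no intercept)
linear_model_fun <- function(beta, intercept = 0) {
  function(m) drop(m %*% beta) + intercept
}
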