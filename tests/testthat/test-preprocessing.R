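test_that("quadratic-fill eligibility follows the 5-value and end-gap rules", {
  M <- NA
  expect_true(eligible_for_quadratic(c(1, 2, M, 4, 5, 6)))
  expect_false(eligible_for_quadratic(c(M, M, 1, 2, 3, 4, 5)))
  expect_false(eligible_for_quadratic(c(1, 2, 3, 4)))          # only 4 values
  expect_true(eligible_for_quadratic(c(M, 1, 2, 3, 4, 5)))     # single end gap ok
  expect_false(eligible_for_quadratic(c(1, 2, 3, 4, 5, M, M))) # double end gap
  expect_error(eligible_for_quadratic(c(M, M, M)), "all-missing")
})

test_that("quadratic fill is exact on quadratic data and matches normal equations on cubics", {
  t <- 1:6
  v <- t^2; v[3] <- NA
  expect_equal(quadratic_fill(v, t)[3], 9, tolerance = 1e-10)

  const <- c(5, 5, NA, 5, 5, 5)
  expect_equal(quadratic_fill(const, t)[3], 5, tolerance = 1e-10)

  # independent oracle: least-squares quadratic by normal equations
  t7 <- 1:7
  v7 <- t7^3; v7[4] <- NA
  obs <- !is.na(v7)
  Xn <- cbind(1, t7, t7^2)
  beta <- solve(t(Xn[obs, ]) %*% Xn[obs, ], t(Xn[obs, ]) %*% v7[obs])
  expect_equal(quadratic_fill(v7, t7)[4], drop(Xn[4, ] %*% beta),
               tolerance = 1e-8)
  # observed entries are never altered
  expect_equal(quadratic_fill(v7, t7)[obs], v7[obs])
})

test_that("quadratic fill recovers random degree-<=2 polynomials exactly", {
  with_seed_test(42, {
    for (i in 1:200) {
      deg <- sample(0:2, 1)
      cf <- rnorm(3) * c(1, 1, 1) * (0:2 <= deg)
      t <- sort(sample(1990:2019, sample(6:15, 1)))
      v <- cf[1] + cf[2] * t + cf[3] * t^2
      miss <- sample(seq_along(t), sample(1:(length(t) - 5), 1))
      vm <- v; vm[miss] <- NA
      if (!eligible_for_quadratic(vm)) next
      expect_equal(quadratic_fill(vm, t), v, tolerance = 1e-6)
    }
  })
})

test_that("mean fill replaces gaps with the series mean", {
  expect_equal(mean_fill(c(1, NA, 3)), c(1, 2, 3))
  expect_equal(mean_fill(c(NA, 5)), c(5, 5))
  expect_equal(mean_fill(c(2, 4, NA, NA, 6)), c(2, 4, 4, 4, 6))
  expect_error(mean_fill(c(NA, NA)), "all-missing")
})

test_that("fill_panel routes series correctly, reports them, and is idempotent", {
  g <- tiny_panel(seed = 9, missing_rate = 0)
  filled0 <- fill_panel(g$panel)
  expect_equal(nrow(fill_report(filled0)), 0)
  expect_equal(filled0$values$value, g$panel$values$value)

  masked <- inject_missingness(g$panel, 0.15, seed = 3)
  filled <- fill_panel(masked)
  expect_false(anyNA(filled$values$value))
  rep <- fill_report(filled)
  n_series_with_gap <- length(unique(paste(
    masked$values$indicator, masked$values$country)[is.na(masked$values$value)]))
  expect_equal(nrow(rep), n_series_with_gap)
  expect_true(all(rep$method %in% c("quadratic", "mean", "excluded")))

  again <- fill_panel(filled)
  expect_equal(again$values, filled$values)
  expect_equal(nrow(fill_report(again)), 0)
})

test_that("an all-missing series is excluded and its country dropped from that year", {
  vals <- expand.grid(country = c("A", "B", "C", "D", "E"), year = 2000:2004,
                      indicator = c("i1", "i2"), stringsAsFactors = FALSE)
  vals$value <- rnorm(nrow(vals)) + (vals$indicator == "i2")
  vals$value[vals$country == "A" & vals$indicator == "i1"] <- NA
  tg <- expand.grid(country = c("A", "B", "C", "D", "E"), year = 2000:2004,
                    stringsAsFactors = FALSE)
  tg$pad <- 700 + rnorm(nrow(tg))
  pan <- indicator_panel(vals, tg, windows = list(i1 = 2000:2004, i2 = 2000:2004))
  filled <- fill_panel(pan)
  expect_true("excluded" %in% fill_report(filled)$method)
  expect_warning(M <- standardize_year(filled, 2001, min_availability = 0.5),
                 "dropping")
  expect_false("A" %in% rownames(M))
})

test_that("per-year standardization gives mean 0 / variance 1 columns", {
  # hand-computed column: population variance 8/3
  vals <- expand.grid(country = c("A", "B", "C"), year = 2000L,
                      indicator = "i1", stringsAsFactors = FALSE)
  vals$value <- c(2, 4, 6)
  tg <- data.frame(country = c("A", "B", "C"), year = 2000L, pad = c(1, 2, 3))
  pan <- indicator_panel(vals, tg, windows = list(i1 = 2000L))
  M <- standardize_year(pan, 2000, min_availability = 0.5)
  expect_equal(unname(M[, "i1"]), c(-1.2247448714, 0, 1.2247448714),
               tolerance = 1e-9)

  g <- tiny_panel(seed = 11, missing_rate = 0.05)
  M2 <- standardize_year(fill_panel(g$panel), 2003)
  expect_true(all(abs(colMeans(M2)) < 1e-10))
  expect_true(all(abs(colMeans(M2^2) - 1) < 1e-10))
  # idempotence to tolerance: standardizing standardized values is a no-op
  mu <- colMeans(M2); va <- colMeans(M2^2) - mu^2
  expect_equal(sweep(sweep(M2, 2, mu), 2, sqrt(va), "/"), M2, tolerance = 1e-9)
})

test_that("constant columns are dropped, not propagated as NaN", {
  vals <- expand.grid(country = c("A", "B", "C", "D"), year = 2000L,
                      indicator = c("i1", "i2"), stringsAsFactors = FALSE)
  vals$value <- ifelse(vals$indicator == "i1", 7, rnorm(nrow(vals)))
  tg <- data.frame(country = c("A", "B", "C", "D"), year = 2000L, pad = 1:4)
  pan <- indicator_panel(vals, tg, windows = list(i1 = 2000L, i2 = 2000L))
  expect_warning(M <- standardize_year(pan, 2000, min_availability = 0.5),
                 "constant")
  expect_equal(colnames(M), "i2")
  expect_false(anyNA(M))
})

test_that("the availability filter excludes sparsely observed indicators", {
  g <- tiny_panel(seed = 13, missing_rate = 0)
  pan <- g$panel
  # knock out 50% of countries for one indicator in one year, pre-fill
  idx <- with(pan$values, indicator == "ind_01" & year == 2002)
  pan$values$value[which(idx)[1:4]] <- NA
  pan <- indicator_panel(pan$values, pan$target, pan$windows)
  filled <- fill_panel(pan)
  M <- standardize_year(filled, 2002, min_availability = 0.8)
  expect_false("ind_01" %in% colnames(M))
  expect_true("ind_01" %in% colnames(standardize_year(filled, 2001)))
})
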