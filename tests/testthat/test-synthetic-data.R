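test_that("panel generation is deterministic and has the configured dimensions", {
  cfg <- panel_config(n_countries = 137, years = 1993:2019, n_indicators = 34,
                      support_size = 5, seed = 3)
  g1 <- generate_panel(cfg)
  g2 <- generate_panel(cfg)
  expect_identical(g1, g2)

  expect_length(g1$panel$countries, 137)
  expect_length(g1$panel$years, 27)
  expect_length(g1$panel$indicators, 34)
  expect_true(all(g1$truth$support %in% g1$panel$indicators))
  # in-window cells only
  for (ind in g1$panel$indicators) {
    yrs <- g1$panel$values$year[g1$panel$values$indicator == ind]
    expect_true(all(yrs %in% g1$panel$windows[[ind]]))
  }
  # target defined everywhere
  expect_equal(nrow(g1$panel$target), 137 * 27)
  expect_false(anyNA(g1$panel$target$pad))
})

test_that("no support and no noise gives a target constant within each year", {
  g <- generate_panel(panel_config(n_countries = 10, years = 2000:2002,
                                   n_indicators = 4, support_size = 0,
                                   noise_sd = 0, missing_rate = 0, seed = 2))
  spread <- tapply(g$panel$target$pad, g$panel$target$year,
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("a noiseless linear target is recovered exactly by a linear solve", {
  cfg <- panel_config(n_countries = 50, years = 2000:2004, n_indicators = 6,
                      support_size = 2, effect_sizes = c(70, -30), noise_sd = 0,
                      missing_rate = 0, seed = 8)
  g <- generate_panel(cfg)
  v <- g$panel$values
  yr <- 2002
  X <- sapply(g$panel$indicators, function(ind) {
    d <- v[v$year == yr & v$indicator == ind, ]
    d$value[match(g$panel$countries, d$country)]
  })
  y <- year_target(g$panel, yr)
  beta <- coef(lm(y ~ X))
  expect_equal(unname(beta[-1][1:2]), c(70, -30), tolerance = 1e-8)
  expect_equal(unname(beta[-1][3:6]), rep(0, 4), tolerance = 1e-8)
})

test_that("missingness injection is binomial at the requested rate", {
  g <- generate_panel(panel_config(n_countries = 50, years = 2000:2009,
                                   n_indicators = 25, support_size = 1,
                                   missing_rate = 0, seed = 4))
  n_cells <- nrow(g$panel$values)
  expect_gte(n_cells, 1e4)
  rate <- 0.02
  counts <- vapply(1:20, function(s) {
    sum(is.na(inject_missingness(g$panel, rate, seed = s)$values$value))
  }, numeric(1))
  # each draw within 4 binomial SDs; the average within 3 SDs of its mean
  sd_bin <- sqrt(n_cells * rate * (1 - rate))
  expect_true(all(abs(counts - n_cells * rate) < 4 * sd_bin))
  expect_lt(abs(mean(counts) - n_cells * rate), 3 * sd_bin / sqrt(20))
  # rate 0 leaves the panel untouched; target is never masked
  expect_identical(inject_missingness(g$panel, 0, seed = 1), g$panel)
  masked <- inject_missingness(g$panel, 0.5, seed = 1)
  expect_false(anyNA(masked$target$pad))
})

test_that("a single entry is masked in about half the seeds at rate 0.5", {
  vals <- data.frame(country = "C1", year = 2000L, indicator = "i1", value = 1.5)
  tg <- data.frame(country = "C1", year = 2000L, pad = 700)
  p1 <- indicator_panel(vals, tg, windows = list(i1 = 2000L))
  hits <- vapply(1:400, function(s) {
    is.na(inject_missingness(p1, 0.5, seed = s)$values$value)
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.5), 3 * 0.5 / sqrt(400))
})

test_that("invalid configuration fields name the offending field", {
  expect_error(panel_config(n_countries = 0), "n_countries")
  expect_error(panel_config(support_size = 40, n_indicators = 5), "support_size")
  expect_error(panel_config(missing_rate = 1), "missing_rate")
  expect_error(panel_config(trend_degree = 3), "trend_degree")
  expect_error(panel_config(effect_sizes = c(1, 2), support_size = 1),
               "effect_sizes")
  g <- tiny_panel()
  expect_error(inject_missingness(g$panel, 1), "rate")
})

test_that("CSV round-trip preserves the panel contents", {
  g <- tiny_panel(seed = 5, missing_rate = 0.1)
  vp <- tempfile(fileext = ".csv"); tp <- tempfile(fileext = ".csv")
  write_panel(g$panel, vp, tp)
  back <- read_panel(vp, tp)
  expect_equal(back$countries, g$panel$countries)
  expect_equal(back$indicators, g$panel$indicators)
  v1 <- g$panel$values[order(g$panel$values$country, g$panel$values$year,
                             g$panel$values$indicator), ]
  v2 <- back$values[order(back$values$country, back$values$year,
                          back$values$indicator), ]
  expect_equal(v1$value, v2$value, tolerance = 1e-12)
  # ground truth serializes
  gt <- tempfile(fileext = ".json")
  write_ground_truth(g$truth, gt)
  expect_equal(jsonlite::read_json(gt)$support[[1]], g$truth$support[1])
  unlink(c(vp, tp, gt))
})
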