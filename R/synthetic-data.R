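#' Configuration for the synthetic indicator-panel generator
#'
#' Describes a country x year x indicator panel of intensive lifestyle
#' indicators together with a dementia-prevalence-like target (PAD, per
#' 100,000, age-standardized) generated from a known sparse subset of the
#' indicators. Defaults mirror the real study setting: 137 countries, 34
#' indicators over 1993-2019, about 2% missingness within each indicator's
#' availability window.
#'
#' @param n_countries number of countries (rows per year).
#' @param years inclusive integer vector of years, e.g. `1993:2019`.
#' @param n_indicators number of indicators generated.
#' @param support_size number of truly predictive indicators.
#' @param effect_sizes numeric vector, one coefficient per support
#'   indicator, on the PAD scale (per 100,000) per standard unit of the
#'   indicator. Default: 60 for each support indicator, which with the
#'   default noise gives a true signal-to-total variance ratio near 0.8.
#' @param noise_sd standard deviation of the additive target noise, in
#'   PAD units. Default 65, the order of magnitude of per-year prediction
#'   RMSE on the real panel.
#' @param missing_rate fraction of in-window entries masked at random
#'   (MCAR), default 0.02.
#' @param availability_windows optional named list mapping indicator name
#'   to the integer years in its availability window. By default windows
#'   are contiguous; roughly a third of indicators get a shortened window
#'   (late start or early end), emulating the availability drop observed
#'   in the most recent years of real repositories.
#' @param trend_degree degree (0, 1 or 2) of the per-(country, indicator)
#'   polynomial time trend.
#' @param interaction logical; add a pairwise interaction term between the
#'   first two support indicators to the target function.
#' @param target_intercept baseline PAD level, default 700 per 100,000.
#' @param seed integer seed controlling the whole generation.
#' @return an object of class `panel_config`.
#' @export
panel_config <- function(n_countries = 137L,
                         years = 1993:2019,
                         n_indicators = 34L,
                         support_size = 5L,
                         effect_sizes = NULL,
                         noise_sd = 65,
                         missing_rate = 0.02,
                         availability_windows = NULL,
                         trend_degree = 2L,
                         interaction = FALSE,
                         target_intercept = 700,
                         seed = 1L) {
  n_countries <- check_count(n_countries, "n_countries")
  n_indicators <- check_count(n_indicators, "n_indicators")
  support_size <- check_count(support_size, "support_size", min = 0L)
  if (!is.numeric(years) || length(years) < 1L || anyNA(years) ||
      any(years != floor(years))) {
    stop_config("years", "must be a non-empty integer vector")
  }
  years <- sort(unique(as.integer(years)))
  if (support_size > n_indicators) {
    stop_config("support_size", "cannot exceed n_indicators")
  }
  if (is.null(effect_sizes)) effect_sizes <- rep(60, support_size)
  if (length(effect_sizes) != support_size || !is.numeric(effect_sizes)) {
    stop_config("effect_sizes", "must be numeric of length support_size")
  }
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  missing_rate <- check_number(missing_rate, "missing_rate",
                               min = 0, max = 1, strict_max = TRUE)
  trend_degree <- check_count(trend_degree, "trend_degree", min = 0L)
  if (trend_degree > 2L) stop_config("trend_degree", "must be 0, 1 or 2")
  interaction <- check_flag(interaction, "interaction")
  target_intercept <- check_number(target_intercept, "target_intercept")
  seed <- check_count(seed, "seed", min = 0L)

  indicators <- sprintf("ind_%02d", seq_len(n_indicators))
  if (!is.null(availability_windows)) {
    if (is.null(names(availability_windows)) ||
        !all(names(availability_windows) %in% indicators)) {
      stop_config("availability_windows",
                  "must be a named list keyed by indicator names")
    }
    for (nm in names(availability_windows)) {
      w <- availability_windows[[nm]]
      if (length(w) == 0L || !all(w %in% years)) {
        stop_config("availability_windows",
                    sprintf("window of '%s' must be a non-empty subset of years", nm))
      }
    }
  }

  structure(list(
    n_countries = n_countries, years = years, n_indicators = n_indicators,
    support_size = support_size, effect_sizes = as.numeric(effect_sizes),
    noise_sd = noise_sd, missing_rate = missing_rate,
    availability_windows = availability_windows,
    trend_degree = trend_degree, interaction = interaction,
    target_intercept = target_intercept, seed = seed,
    indicators = indicators
  ), class = "panel_config")
}

default_windows <- function(config) {
  years <- config$years
  n_years <- length(years)
  windows <- vector("list", config$n_indicators)
  names(windows) <- config$indicators
  # ~1/3 of indicators get a shortened contiguous window; shortening is
  # biased toward early endings to emulate the late-year availability drop.
  shorten <- stats::runif(config$n_indicators) < 1 / 3
  for (i in seq_len(config$n_indicators)) {
    if (!shorten[i] || n_years < 4L) {
      windows[[i]] <- years
    } else if (stats::runif(1) < 0.7) {
      last <- sample(seq(ceiling(0.6 * n_years), n_years - 1L), 1L)
      windows[[i]] <- years[seq_len(last)]
    } else {
      first <- sample(2:floor(0.4 * n_years + 1), 1L)
      windows[[i]] <- years[first:n_years]
    }
  }
  windows
}

#' Construct an indicator panel object
#'
#' @param values data.frame with columns `country`, `year`, `indicator`,
#'   `value`; one row per in-window (country, year, indicator) cell, with
#'   `NA` value meaning missing-within-window.
#' @param target data.frame with columns `country`, `year`, `pad`.
#' @param windows named list mapping indicator to its availability years.
#' @return an object of class `indicator_panel` with components
#'   `countries`, `years`, `indicators`, `values`, `target`, `windows`,
#'   and `n_observed` (pre-fill non-missing country counts per
#'   indicator-year, used by the per-year availability filter).
#' @export
indicator_panel <- function(values, target, windows) {
  stopifnot(is.data.frame(values),
            all(c("country", "year", "indicator", "value") %in% names(values)),
            is.data.frame(target),
            all(c("country", "year", "pad") %in% names(target)))
  values$country <- as.character(values$country)
  values$indicator <- as.character(values$indicator)
  values$year <- as.integer(values$year)
  target$country <- as.character(target$country)
  target$year <- as.integer(target$year)
  countries <- sort(unique(c(values$country, target$country)))
  years <- sort(unique(c(values$year, target$year)))
  indicators <- sort(unique(values$indicator))
  if (is.null(windows)) {
    windows <- lapply(split(values$year, values$indicator),
                      function(y) sort(unique(y)))
    windows <- windows[indicators]
  }
  for (ind in indicators) {
    bad <- values$indicator == ind & !(values$year %in% windows[[ind]])
    if (any(bad)) {
      stop(sprintf("indicator '%s' has values outside its availability window", ind))
    }
  }
  values <- values[order(values$indicator, values$country, values$year), ]
  rownames(values) <- NULL
  target <- target[order(target$country, target$year), ]
  rownames(target) <- NULL
  obs <- values[!is.na(values$value), c("indicator", "year")]
  n_observed <- if (nrow(obs) == 0L) {
    data.frame(indicator = character(), year = integer(), n_obs = integer())
  } else {
    agg <- stats::aggregate(rep(1L, nrow(obs)),
                            by = list(indicator = obs$indicator, year = obs$year),
                            FUN = sum)
    names(agg)[3] <- "n_obs"
    agg
  }
  structure(list(countries = countries, years = years, indicators = indicators,
                 values = values, target = target, windows = windows,
                 n_observed = n_observed),
            class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  n_na <- sum(is.na(x$values$value))
  cat(sprintf(paste0("indicator_panel: %d countries x %d years x %d indicators\n",
                     "  %d in-window cells (%d missing, %.1f%%); target '%s' on %d rows\n"),
              length(x$countries), length(x$years), length(x$indicators),
              nrow(x$values), n_na, 100 * n_na / max(1, nrow(x$values)),
              "pad", nrow(x$target)))
  invisible(x)
}

#' Generate a synthetic indicator panel with known ground truth
#'
#' Indicator trajectories follow per-(country, indicator) polynomial time
#' trends of the configured degree plus i.i.d. observation noise. The
#' target is linear in the support indicators (optionally with one
#' pairwise interaction) plus Gaussian noise, computed from the complete
#' underlying values so that it is defined for every (country, year).
#' In-window missingness is then injected at `missing_rate` (MCAR).
#' Fully reproducible from `config$seed`.
#'
#' @param config a [panel_config()].
#' @return a list with components `panel` (an [indicator_panel()]) and
#'   `truth` (class `ground_truth`: support names, effect sizes, target
#'   description, noise sd, intercept).
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "panel_config")) {
    stop("config must be a panel_config object")
  }
  with_seed(config$seed, {
    countries <- sprintf("C%03d", seq_len(config$n_countries))
    years <- config$years
    indicators <- config$indicators
    n_y <- length(years)
    t_c <- (years - mean(years)) / max(1, (max(years) - min(years)) / 2)

    windows <- config$availability_windows
    if (is.null(windows)) windows <- default_windows(config)
    for (ind in setdiff(indicators, names(windows))) windows[[ind]] <- years
    windows <- windows[indicators]

    # underlying complete values: level + trend + observation noise
    vals <- array(NA_real_, dim = c(config$n_countries, n_y, config$n_indicators),
                  dimnames = list(countries, as.character(years), indicators))
    for (j in seq_along(indicators)) {
      a <- stats::rnorm(config$n_countries, 0, 1)
      b <- if (config$trend_degree >= 1L) stats::rnorm(config$n_countries, 0, 0.3)
           else rep(0, config$n_countries)
      cc <- if (config$trend_degree >= 2L) stats::rnorm(config$n_countries, 0, 0.15)
            else rep(0, config$n_countries)
      trend <- outer(b, t_c) + outer(cc, t_c^2)
      eps <- matrix(stats::rnorm(config$n_countries * n_y, 0, 0.1),
                    config$n_countries, n_y)
      vals[, , j] <- a + trend + eps
    }

    support <- indicators[seq_len(config$support_size)]
    signal <- matrix(0, config$n_countries, n_y)
    for (s in seq_along(support)) {
      signal <- signal + config$effect_sizes[s] * vals[, , support[s]]
    }
    if (config$interaction && config$support_size >= 2L) {
      beta_int <- mean(abs(config$effect_sizes))
      signal <- signal + beta_int * vals[, , support[1]] * vals[, , support[2]]
    }
    pad <- config$target_intercept + signal +
      matrix(stats::rnorm(config$n_countries * n_y, 0, config$noise_sd),
             config$n_countries, n_y)

    keep <- do.call(rbind, lapply(seq_along(indicators), function(j) {
      yrs <- windows[[indicators[j]]]
      expand.grid(country = countries, year = yrs,
                  indicator = indicators[j], stringsAsFactors = FALSE)
    }))
    keep$value <- vals[cbind(match(keep$country, countries),
                             match(keep$year, years),
                             match(keep$indicator, indicators))]
    target <- expand.grid(country = countries, year = years,
                          stringsAsFactors = FALSE)
    target$pad <- pad[cbind(match(target$country, countries),
                            match(target$year, years))]

    panel <- indicator_panel(keep, target, windows)
    panel <- inject_missingness(panel, config$missing_rate,
                                seed = derive_seed(config$seed, 104729L))
    truth <- structure(list(
      support = support,
      effect_sizes = stats::setNames(config$effect_sizes, support),
      target_function = if (config$interaction)
        "linear in support indicators plus one pairwise interaction (first two)"
      else "linear in support indicators",
      interaction = config$interaction,
      noise_sd = config$noise_sd,
      intercept = config$target_intercept
    ), class = "ground_truth")
    list(panel = panel, truth = truth)
  })
}

#' Mask a random fraction of in-window panel entries
#'
#' Sets the expected fraction `rate` of in-window values to missing,
#' uniformly at random (MCAR). Entries outside availability windows do
#' not exist in the panel and are untouched; the target is never masked.
#'
#' @param panel an [indicator_panel()].
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed (NULL: current RNG stream).
#' @return the masked panel.
#' @export
inject_missingness <- function(panel, rate, seed = NULL) {
  stopifnot(inherits(panel, "indicator_panel"))
  rate <- check_number(rate, "rate", min = 0, max = 1, strict_max = TRUE)
  if (rate == 0) return(panel)
  with_seed(seed, {
    mask <- stats::runif(nrow(panel$values)) < rate
    panel$values$value[mask] <- NA_real_
    indicator_panel(panel$values, panel$target, panel$windows)
  })
}

#' Write a panel to long-format CSV files
#'
#' @param panel an [indicator_panel()].
#' @param values_path CSV path for `country,year,indicator,value` rows;
#'   missing values written as empty fields.
#' @param target_path CSV path for `country,year,pad` rows.
#' @export
write_panel <- function(panel, values_path, target_path) {
  stopifnot(inherits(panel, "indicator_panel"))
  utils::write.csv(panel$values[, c("country", "year", "indicator", "value")],
                   values_path, row.names = FALSE, na = "")
  utils::write.csv(panel$target[, c("country", "year", "pad")],
                   target_path, row.names = FALSE, na = "")
  invisible(panel)
}

#' Read a panel from long-format CSV files
#'
#' Availability windows are taken as the set of years each indicator has
#' rows for (present rows with an empty value field count as in-window
#' missing entries).
#'
#' @param values_path CSV with header `country,year,indicator,value`.
#' @param target_path CSV with header `country,year,pad`.
#' @return an [indicator_panel()].
#' @export
read_panel <- function(values_path, target_path) {
  values <- utils::read.csv(values_path, stringsAsFactors = FALSE,
                            colClasses = c(country = "character",
                                           year = "integer",
                                           indicator = "character",
                                           value = "numeric"))
  target <- utils::read.csv(target_path, stringsAsFactors = FALSE,
                            colClasses = c(country = "character",
                                           year = "integer",
                                           pad = "numeric"))
  indicator_panel(values, target, windows = NULL)
}

#' Serialize ground truth to JSON
#' @param truth a `ground_truth` object.
#' @param path output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
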