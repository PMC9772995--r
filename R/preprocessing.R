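#' Eligibility of a series for quadratic interpolation
#'
#' A per-(indicator, country) series can be filled by a quadratic-in-year
#' fit when it holds at least 5 observed values within the availability
#' period and has no run of two or more consecutive missing entries at
#' either end. A single missing value at an end is allowed (it is
#' extrapolated by the fitted quadratic).
#'
#' @param values numeric vector over the availability window, `NA` = missing.
#' @return TRUE if the quadratic rule applies, FALSE if the series must
#'   fall back to mean filling.
#' @export
eligible_for_quadratic <- function(values) {
  if (length(values) == 0L) stop("empty series")
  miss <- is.na(values)
  if (all(miss)) stop("all-missing series cannot be filled")
  if (sum(!miss) < 5L) return(FALSE)
  lead_run <- which.min(miss) - 1L   # length of leading NA run
  tail_run <- which.min(rev(miss)) - 1L
  lead_run < 2L && tail_run < 2L
}

#' Fill a series by least-squares quadratic interpolation in the year
#'
#' Fits `value ~ year + year^2` on the observed entries and replaces each
#' missing entry with the fitted value at its year. Observed entries are
#' unchanged. Exact on any series generated by a polynomial of degree
#' at most 2.
#'
#' @param values numeric vector with `NA` for missing entries.
#' @param years numeric vector of years, parallel to `values`, strictly
#'   increasing.
#' @return the filled numeric vector.
#' @export
quadratic_fill <- function(values, years) {
  stopifnot(length(values) == length(years), !is.unsorted(years, strictly = TRUE))
  if (!eligible_for_quadratic(values)) {
    stop("series not eligible for quadratic fill; use mean_fill")
  }
  miss <- is.na(values)
  if (!any(miss)) return(values)
  t0 <- years - mean(years)    # centering for conditioning
  X <- cbind(1, t0, t0^2)
  beta <- stats::lm.fit(X[!miss, , drop = FALSE], values[!miss])$coefficients
  beta[is.na(beta)] <- 0
  values[miss] <- drop(X[miss, , drop = FALSE] %*% beta)
  values
}

#' Fill a series with the mean of its observed values
#'
#' Fallback rule for series not eligible for the quadratic fit: every
#' missing entry is replaced by the arithmetic mean of the observed
#' entries of that same (indicator, country) series.
#'
#' @param values numeric vector with `NA` for missing entries; at least
#'   one observed value required.
#' @return the filled numeric vector.
#' @export
mean_fill <- function(values) {
  miss <- is.na(values)
  if (all(miss)) stop("all-missing series cannot be mean-filled")
  values[miss] <- mean(values[!miss])
  values
}

#' Fill every missing in-window entry of a panel
#'
#' Routes each (indicator, country) series to [quadratic_fill()] when
#' eligible and to [mean_fill()] otherwise. Series with no observed value
#' at all are left missing and flagged as excluded (they are dropped from
#' the affected per-year design matrices downstream). The routing report
#' is attached as attribute `"fill_report"` (a data.frame
#' `indicator,country,method,n_filled`) and readable via [fill_report()].
#' Idempotent: filling a filled panel changes nothing.
#'
#' @param panel an [indicator_panel()].
#' @return the filled panel.
#' @export
fill_panel <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  v <- panel$values
  ord <- order(v$indicator, v$country, v$year)
  v <- v[ord, ]
  key <- paste(v$indicator, v$country, sep = "\r")
  idx_by_series <- split(seq_len(nrow(v)), key)
  has_na <- vapply(idx_by_series, function(i) anyNA(v$value[i]), logical(1))
  report <- list()
  for (k in names(idx_by_series)[has_na]) {
    idx <- idx_by_series[[k]]
    series <- v$value[idx]
    n_miss <- sum(is.na(series))
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (all(is.na(series))) {
      method <- "excluded"
    } else if (eligible_for_quadratic(series)) {
      v$value[idx] <- quadratic_fill(series, v$year[idx])
      method <- "quadratic"
    } else {
      v$value[idx] <- mean_fill(series)
      method <- "mean"
    }
    report[[k]] <- data.frame(indicator = parts[1], country = parts[2],
                              method = method, n_filled = n_miss,
                              stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, c(report, make.row.names = FALSE))
            else data.frame(indicator = character(), country = character(),
                            method = character(), n_filled = integer(),
                            stringsAsFactors = FALSE)
  out <- indicator_panel(v, panel$target, panel$windows)
  # keep pre-fill availability counts for the per-year inclusion filter
  out$n_observed <- panel$n_observed
  attr(out, "fill_report") <- report
  out
}

#' Retrieve the fill report of a filled panel
#' @param panel a panel returned by [fill_panel()].
#' @return data.frame `indicator,country,method,n_filled` (one row per
#'   series that had at least one missing entry).
#' @export
fill_report <- function(panel) {
  rep <- attr(panel, "fill_report")
  if (is.null(rep)) stop("panel has no fill report; run fill_panel() first")
  rep
}

#' Per-year standardized design matrix
#'
#' Builds the countries x indicators matrix for one year and standardizes
#' each indicator column over countries to mean 0, variance 1 (population
#' variance by default). An indicator enters the year's matrix only if
#' its availability window covers the year and at least
#' `min_availability` of the countries had an observed (pre-fill) value
#' for that year. Constant columns are dropped with a warning, as are
#' countries with an unfillable (excluded) series among the included
#' indicators.
#'
#' @param panel a filled [indicator_panel()] (see [fill_panel()]).
#' @param year the year to extract.
#' @param min_availability minimum pre-fill fraction of countries with an
#'   observed value (default 0.8).
#' @param variance "population" (divide by n, the default) or "sample"
#'   (divide by n - 1).
#' @return a numeric matrix with countries as rownames and indicators as
#'   colnames, attribute `"year"`; zero columns if no indicator qualifies.
#' @export
standardize_year <- function(panel, year, min_availability = 0.8,
                             variance = c("population", "sample")) {
  stopifnot(inherits(panel, "indicator_panel"))
  variance <- match.arg(variance)
  year <- as.integer(year)
  if (!year %in% panel$years) stop(sprintf("year %d not in panel", year))
  n_c <- length(panel$countries)

  in_window <- vapply(panel$indicators,
                      function(ind) year %in% panel$windows[[ind]], logical(1))
  nobs <- panel$n_observed
  nobs_year <- stats::setNames(rep(0L, length(panel$indicators)), panel$indicators)
  sel <- nobs$year == year
  nobs_year[nobs$indicator[sel]] <- nobs$n_obs[sel]
  keep <- panel$indicators[in_window & nobs_year >= min_availability * n_c]
  if (length(keep) == 0L) {
    m <- matrix(numeric(0), nrow = n_c, ncol = 0,
                dimnames = list(panel$countries, NULL))
    attr(m, "year") <- year
    return(m)
  }

  v <- panel$values[panel$values$year == year & panel$values$indicator %in% keep, ]
  m <- matrix(NA_real_, n_c, length(keep),
              dimnames = list(panel$countries, keep))
  m[cbind(match(v$country, panel$countries), match(v$indicator, keep))] <- v$value

  # countries with an excluded (all-missing) series are dropped row-wise
  bad_rows <- rowSums(is.na(m)) > 0
  if (any(bad_rows)) {
    warning(sprintf("dropping %d countries with unfillable series in %d",
                    sum(bad_rows), year))
    m <- m[!bad_rows, , drop = FALSE]
  }

  mu <- colMeans(m)
  n <- nrow(m)
  va <- if (variance == "population") colMeans(m^2) - mu^2
        else apply(m, 2, stats::var)
  const <- va <= .Machine$double.eps * 100
  if (any(const)) {
    warning(sprintf("dropping %d constant indicator(s) in %d: %s", sum(const),
                    year, paste(colnames(m)[const], collapse = ", ")))
    m <- m[, !const, drop = FALSE]
    mu <- mu[!const]; va <- va[!const]
  }
  m <- sweep(sweep(m, 2, mu, "-"), 2, sqrt(va), "/")
  attr(m, "year") <- year
  m
}

#' Target vector aligned to a design matrix
#'
#' @param panel an [indicator_panel()].
#' @param year the year.
#' @param countries country identifiers (defaults to all panel countries);
#'   typically `rownames()` of the matrix from [standardize_year()].
#' @return named numeric vector of PAD values.
#' @export
year_target <- function(panel, year, countries = panel$countries) {
  stopifnot(inherits(panel, "indicator_panel"))
  tg <- panel$target[panel$target$year == as.integer(year), ]
  out <- stats::setNames(tg$pad[match(countries, tg$country)], countries)
  if (anyNA(out)) stop(sprintf("target undefined for some countries in %d", year))
  out
}
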