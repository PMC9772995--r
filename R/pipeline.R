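#' Run the full per-year workflow for one year
#'
#' Stages, in order: per-year standardized design matrix (availability
#' filter + gap-filled values), shadow-feature selection, repeated-CV
#' random-forest regression on the selected features, per-country
#' Shapley attribution aggregated over the same CV scheme, and the
#' 25%-of-total retention rule. Deterministic given `seed` (stage seeds
#' are derived with [derive_seed()], so other years are unaffected by
#' adding or removing a year).
#'
#' @param panel a gap-filled [indicator_panel()] (see [fill_panel()]).
#' @param year the year to run.
#' @param boruta a [boruta_config()] (its `seed` is overridden).
#' @param cv a [cv_config()] (its `seed` is overridden).
#' @param shap_mode "exact_subsets" or "sampled" (see [shap_over_cv()]).
#' @param background_size Shapley background rows per fold model.
#' @param min_availability per-year indicator inclusion threshold
#'   (fraction of countries observed before fill, default 0.8).
#' @param use_selected train the regression on Boruta-selected features
#'   (default TRUE; falls back to all features when none is selected).
#' @param seed master seed for this year.
#' @return object of class `year_result` (`year`, `boruta`, `report`,
#'   `shap`, `retained`, `features`), or NULL when the year's design
#'   matrix is empty or too small (the year is skipped with a message).
#' @export
run_year <- function(panel, year, boruta = boruta_config(), cv = cv_config(),
                     shap_mode = c("exact_subsets", "sampled"),
                     background_size = 50L, min_availability = 0.8,
                     use_selected = TRUE, seed = 1L) {
  shap_mode <- match.arg(shap_mode)
  M <- standardize_year(panel, year, min_availability = min_availability)
  if (ncol(M) == 0L || nrow(M) < 2L * cv$k) {
    message(sprintf("year %d skipped: design matrix %d x %d is too small",
                    year, nrow(M), ncol(M)))
    return(NULL)
  }
  y <- year_target(panel, year, countries = rownames(M))

  boruta$seed <- derive_seed(seed, 11L, year)
  sel <- boruta_select(M, y, boruta, year = year)
  features <- if (use_selected && length(sel$selected)) sel$selected
              else colnames(M)
  Xf <- M[, features, drop = FALSE]

  cv$seed <- derive_seed(seed, 12L, year)
  report <- regression_report(Xf, y, cv, year = year)

  if (shap_mode == "exact_subsets" && ncol(Xf) > 15L) shap_mode <- "sampled"
  shap <- shap_over_cv(Xf, y, cv, year = year, mode = shap_mode,
                       background_size = background_size)
  retained <- retain_features(shap)

  structure(list(year = year, boruta = sel, report = report, shap = shap,
                 retained = retained, features = features,
                 countries = rownames(M)),
            class = "year_result")
}

#' @export
print.year_result <- function(x, ...) {
  cat(sprintf("year_result [%d]: %d features after selection; R2 %.3f +/- %.3f; retained: %s\n",
              x$year, length(x$features), x$report$r2[1], x$report$r2[2],
              if (length(x$retained$retained))
                paste(x$retained$retained, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Run the pipeline over all years and assemble cross-year outputs
#'
#' Fills the panel if needed, runs [run_year()] for every requested year
#' (a failing or skipped year does not abort the others), builds the
#' cross-year feature competition network from the yearly importance
#' tables, and assembles the per-year performance summary, the
#' year x indicator importance matrix (with explicit `discarded` /
#' `missing` markers), and the retained-feature listing. With `out_dir`
#' set, all tables, the GraphML network and per-year JSON results are
#' written there.
#'
#' @inheritParams run_year
#' @param years years to run (default: all panel years).
#' @param out_dir optional output directory.
#' @return object of class `pipeline_result`: `years` (list of
#'   `year_result`), `network`, `summary`, `importance_matrix`,
#'   `retained`, `skipped`.
#' @export
run_all <- function(panel, years = panel$years, boruta = boruta_config(),
                    cv = cv_config(), shap_mode = "exact_subsets",
                    background_size = 50L, min_availability = 0.8,
                    use_selected = TRUE, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (is.null(attr(panel, "fill_report"))) panel <- fill_panel(panel)
  results <- list()
  skipped <- integer(0)
  for (yr in years) {
    res <- tryCatch(
      run_year(panel, yr, boruta = boruta, cv = cv, shap_mode = shap_mode,
               background_size = background_size,
               min_availability = min_availability,
               use_selected = use_selected, seed = seed),
      error = function(e) {
        message(sprintf("year %d failed: %s", yr, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) skipped <- c(skipped, yr) else results[[as.character(yr)]] <- res
  }
  if (length(results) == 0L) stop("no year completed")

  boruta_results <- lapply(results, `[[`, "boruta")
  network <- build_network(boruta_results)
  summary <- summary_table(results)
  imp_mat <- importance_matrix(results, panel)
  retained <- do.call(rbind, lapply(results, function(r) {
    data.frame(year = r$year,
               retained = if (length(r$retained$retained))
                 paste(r$retained$retained, collapse = ";") else "",
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  out <- structure(list(years = results, network = network, summary = summary,
                        importance_matrix = imp_mat, retained = retained,
                        skipped = skipped, seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d years completed (%d skipped), network %d nodes / %d edges\n",
              length(x$years), length(x$skipped),
              igraph::vcount(x$network), igraph::ecount(x$network)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Per-year performance summary table
#'
#' @param results list of `year_result` objects.
#' @return data.frame
#'   `year,r2_mean,r2_sd,mape_mean,mape_sd,rmse_mean,rmse_sd,p_value,n_features,n_countries`.
#' @export
summary_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(year = r$year,
               r2_mean = r$report$r2[[1]], r2_sd = r$report$r2[[2]],
               mape_mean = r$report$mape[[1]], mape_sd = r$report$mape[[2]],
               rmse_mean = r$report$rmse[[1]], rmse_sd = r$report$rmse[[2]],
               p_value = r$report$p_value,
               n_features = length(r$features),
               n_countries = length(r$countries),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Year x indicator importance matrix with availability markers
#'
#' Mean Boruta importance per (year, indicator); `"discarded"` marks
#' indicators rejected by the selector for that year, `"missing"` marks
#' indicators that did not enter that year's design matrix (out of
#' window or below the availability threshold).
#'
#' @param results list of `year_result` objects.
#' @param panel the panel the results were computed from.
#' @return character data.frame, years as rows, indicators as columns.
#' @export
importance_matrix <- function(results, panel) {
  inds <- panel$indicators
  yrs <- vapply(results, `[[`, integer(1), "year")
  m <- matrix("missing", length(yrs), length(inds),
              dimnames = list(as.character(yrs), inds))
  for (r in results) {
    imp <- r$boruta$importance
    row <- as.character(r$year)
    m[row, names(imp)] <- sprintf("%.6g", imp)
    discarded <- setdiff(names(imp), r$boruta$selected)
    m[row, discarded] <- "discarded"
  }
  as.data.frame(m, stringsAsFactors = FALSE)
}

year_result_to_list <- function(r) {
  list(
    year = r$year,
    features = r$features,
    boruta = list(selected = r$boruta$selected, rejected = r$boruta$rejected,
                  tentative = r$boruta$tentative,
                  importance = as.list(r$boruta$importance),
                  hit_counts = as.list(r$boruta$hit_counts)),
    report = list(n = r$report$n, r2 = as.list(r$report$r2),
                  rmse = as.list(r$report$rmse), mape = as.list(r$report$mape),
                  p_value = r$report$p_value),
    shap = list(baseline = r$shap$baseline,
                mean_abs = as.list(colMeans(abs(r$shap$values)))),
    retained = r$retained$retained)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the per-year summary CSV, the importance matrix CSV, the
#' retained-feature listing, the GraphML network and edge list, per-year
#' result JSON files and per-year SHAP matrices (countries as rows).
#'
#' @param result a [run_all()] result.
#' @param out_dir output directory (created if absent).
#' @export
write_pipeline_result <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(year = rownames(result$importance_matrix),
                         result$importance_matrix),
                   file.path(out_dir, "importance_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(result$retained, file.path(out_dir, "retained_features.csv"),
                   row.names = FALSE)
  write_network(result$network,
                graphml_path = file.path(out_dir, "competition_network.graphml"),
                edgelist_path = file.path(out_dir, "competition_edges.csv"))
  for (r in result$years) {
    jsonlite::write_json(year_result_to_list(r),
                         file.path(out_dir, sprintf("year_%d.json", r$year)),
                         auto_unbox = TRUE, digits = NA)
    shap_df <- data.frame(country = r$shap$countries, r$shap$values,
                          check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(shap_df,
                     file.path(out_dir, sprintf("shap_%d.csv", r$year)),
                     row.names = FALSE)
  }
  invisible(result)
}

#' Read a pipeline run configuration from YAML or JSON
#'
#' The file may contain either `panel`/`target` CSV paths or a
#' `synthetic` block of [panel_config()] fields (exactly one of the
#' two), plus optional `years`, `boruta`, `cv`, `shap_mode`,
#' `background_size`, `min_availability`, `seed` and `out_dir` entries.
#'
#' @param path YAML (`.yml`/`.yaml`, requires the yaml package) or JSON
#'   file.
#' @return a validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  has_paths <- !is.null(cfg$panel) && !is.null(cfg$target)
  has_synth <- !is.null(cfg$synthetic)
  if (has_paths == has_synth) {
    stop("config must contain exactly one of {panel+target paths, synthetic block}")
  }
  structure(cfg, class = "run_config")
}

#' Run the pipeline from a configuration
#'
#' @param config a [read_run_config()] result or equivalent list.
#' @return a [run_all()] result.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$synthetic)) {
    pc <- do.call(panel_config, config$synthetic)
    panel <- generate_panel(pc)$panel
  } else {
    panel <- read_panel(config$panel, config$target)
  }
  args <- list(panel = panel)
  if (!is.null(config$years)) args$years <- as.integer(config$years)
  if (!is.null(config$boruta)) args$boruta <- do.call(boruta_config, config$boruta)
  if (!is.null(config$cv)) args$cv <- do.call(cv_config, config$cv)
  for (nm in c("shap_mode", "background_size", "min_availability",
               "use_selected", "seed", "out_dir")) {
    if (!is.null(config[[nm]])) args[[nm]] <- config[[nm]]
  }
  do.call(run_all, args)
}
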