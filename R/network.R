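#' Binary year-by-year comparison vector of two features
#'
#' For every year in which both features carry an importance value, the
#' entry is 1 when feature i strictly out-ranks feature j and 0 otherwise
#' (ties count as 0). Equality is exact on the stored importances, which
#' are averages of finite sums.
#'
#' @param imp_i,imp_j numeric vectors of importances named by year.
#' @return integer 0/1 vector named by the shared years (possibly empty).
#' @export
comparison_vector <- function(imp_i, imp_j) {
  yrs <- intersect(names(imp_i), names(imp_j))
  yrs <- yrs[order(as.integer(yrs))]
  stats::setNames(as.integer(imp_i[yrs] > imp_j[yrs]), yrs)
}

#' Shannon entropy of a binary sequence, in bits
#'
#' `H = -p log2 p - (1 - p) log2(1 - p)` with `p` the fraction of ones;
#' 0 when the sequence is constant, and by convention 0 for an empty
#' sequence (no competition observed).
#'
#' @param v a 0/1 vector.
#' @return entropy in `[0, 1]` bits.
#' @export
shannon_entropy <- function(v) {
  if (length(v) == 0L) return(0)
  if (!all(v %in% c(0, 1))) stop("v must be binary")
  p <- mean(v)
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Build the feature competition network
#'
#' Nodes are all features appearing in at least one yearly importance
#' table (selected or not). For every pair, the edge weight is the
#' Shannon entropy of the binary record of which feature out-ranked the
#' other across their shared years; zero-weight pairs (one feature always
#' dominant, or fewer than two shared years) carry no edge. Node
#' attributes: `availability` (number of yearly tables containing the
#' feature) and `mean_importance` (mean importance over those years).
#'
#' @param results a list of [boruta_select()] results, or a data.frame
#'   as returned by [importance_table()].
#' @return an `igraph` undirected graph with edge attribute `weight`.
#' @export
build_network <- function(results) {
  tab <- if (is.data.frame(results)) results else importance_table(results)
  stopifnot(all(c("year", "indicator", "importance") %in% names(tab)))
  if (nrow(tab) == 0L) stop("need at least one year of importance results")

  feats <- sort(unique(tab$indicator))
  by_feat <- lapply(split(tab, tab$indicator), function(d) {
    stats::setNames(d$importance, as.character(d$year))
  })
  availability <- vapply(by_feat, length, integer(1))[feats]
  mean_imp <- vapply(by_feat, mean, numeric(1))[feats]

  edges <- list()
  n <- length(feats)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- shannon_entropy(comparison_vector(by_feat[[feats[i]]],
                                             by_feat[[feats[j]]]))
      if (w > 0) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = feats[i], to = feats[j], weight = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character(),
                           weight = numeric(), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = feats, availability = unname(availability),
                          mean_importance = unname(mean_imp),
                          stringsAsFactors = FALSE))
}

#' Node-level summary of a competition network
#'
#' Degree (number of competitors), strength (sum of incident entropy
#' weights), mean importance and availability per feature — the
#' quantities behind the degree-versus-importance "horseshoe" scatter:
#' features that are steadily at the top (or bottom) of the yearly
#' rankings have low degree, while features that keep switching ranks
#' accumulate high-entropy edges.
#'
#' @param network an `igraph` graph from [build_network()].
#' @return data.frame `feature,degree,strength,mean_importance,availability`.
#' @export
node_summary <- function(network) {
  stopifnot(inherits(network, "igraph"))
  data.frame(
    feature = igraph::V(network)$name,
    degree = igraph::degree(network),
    strength = igraph::strength(network, weights = igraph::E(network)$weight),
    mean_importance = igraph::V(network)$mean_importance,
    availability = igraph::V(network)$availability,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Export a competition network
#'
#' @param network an `igraph` graph from [build_network()].
#' @param graphml_path optional path for a GraphML export.
#' @param edgelist_path optional path for a CSV edge list
#'   (`feature_i,feature_j,weight`).
#' @export
write_network <- function(network, graphml_path = NULL, edgelist_path = NULL) {
  stopifnot(inherits(network, "igraph"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(network, what = "edges")
    names(el)[1:2] <- c("feature_i", "feature_j")
    utils::write.csv(el, edgelist_path, row.names = FALSE)
  }
  invisible(network)
}
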