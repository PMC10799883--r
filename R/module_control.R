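#' Mean shortest-path distance from a source set to a module
#'
#' Average of directed shortest-path lengths over all (source, module-node)
#' pairs. A pair whose source equals the module node contributes 0. Pairs
#' with no directed path are excluded from the average and counted
#' separately (`strict = TRUE` errors on any unreachable pair instead).
#' Values close to 1 indicate the sources sit directly upstream of the
#' module.
#'
#' @param network a [directed_network()].
#' @param sources,module non-empty character vectors of node identifiers.
#' @param strict error on unreachable pairs instead of excluding them.
#' @return `list(mean_distance, unreachable_pairs)`.
#' @export
mean_distance <- function(network, sources, module, strict = FALSE) {
  check_node_sets(network, sources, module)
  g <- as_igraph(network)
  d <- igraph::distances(g, v = sources, to = module, mode = "out")
  unreachable <- sum(!is.finite(d))
  if (strict && unreachable > 0L) {
    stop(unreachable, " unreachable (source, module-node) pair(s)")
  }
  if (unreachable == length(d)) stop("all (source, module-node) pairs unreachable")
  list(mean_distance = mean(d[is.finite(d)]),
       unreachable_pairs = unreachable)
}

#' Number of direct links from a source set into a module
#'
#' Counts directed edges from any source into any module node: each module
#' node contributes the number of distinct sources pointing at it, so a
#' module node fed by several sources is counted once per source. Edges from
#' sources that are themselves module members count too.
#'
#' @inheritParams mean_distance
#' @return Non-negative integer.
#' @export
links_metric <- function(network, sources, module) {
  check_node_sets(network, sources, module)
  idx <- match(module, network$nodes)
  src <- network$nodes %in% sources
  sum(vapply(idx, function(u) sum(src[network$in_nbrs[[u]]]), numeric(1)))
}

#' Fraction of module nodes covered by a source set
#'
#' The share of module nodes with at least one incoming edge from a source;
#' with `|module|` nodes it can take only `|module| + 1` distinct values.
#' A value of 1 means every module node is directly reachable in one step.
#'
#' @inheritParams mean_distance
#' @return Real in `[0, 1]`.
#' @export
cov_metric <- function(network, sources, module) {
  check_node_sets(network, sources, module)
  idx <- match(module, network$nodes)
  src <- network$nodes %in% sources
  mean(vapply(idx, function(u) as.numeric(any(src[network$in_nbrs[[u]]])),
              numeric(1)))
}

check_node_sets <- function(network, sources, module) {
  stopifnot(inherits(network, "directed_network"),
            length(sources) > 0L, length(module) > 0L)
  missing <- setdiff(c(sources, module), network$nodes)
  if (length(missing)) {
    stop("node(s) not in network: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Module-control metrics with a randomization test
#'
#' Computes the observed mean distance, links and coverage of a source set
#' against a module, then draws `trials` node sets of the same size
#' uniformly without replacement from the whole network (optionally
#' excluding the module itself), recomputes each metric per draw, and
#' reports one-tailed empirical p-values: lower tail for the mean distance
#' (a controlling set should be *close*), upper tail for links and coverage.
#' The p-value is the raw fraction of null draws at least as extreme as the
#' observed value; it can be exactly 0 when no draw reaches it (no
#' small-sample correction is applied; the conservative alternative adds 1
#' to numerator and denominator). Null draws for which every
#' (draw, module-node) pair is unreachable contribute `Inf` to the mean
#' distance null.
#'
#' @inheritParams mean_distance
#' @param trials number of random draws (default 10000).
#' @param seed integer seed for the draws; fixing it makes the null
#'   distributions bit-reproducible.
#' @param metrics subset of `c("mean_distance", "links", "cov")` to test.
#' @param exclude_module draw null sets from outside the module only.
#' @return An object of class `module_control_report`: `sources`, `module`,
#'   `observed` (named list incl. `unreachable_pairs`), `null` (named list
#'   of length-`trials` numeric vectors), `p_values`, `trials`, `seed`.
#' @export
module_control <- function(network, sources, module, trials = 10000,
                           seed = 1L,
                           metrics = c("mean_distance", "links", "cov"),
                           exclude_module = FALSE) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  check_node_sets(network, sources, module)
  stopifnot(trials >= 1)
  pool <- if (exclude_module) setdiff(network$nodes, module) else network$nodes
  if (length(sources) > length(pool)) {
    stop("source set larger than the sampling pool")
  }

  observed <- list()
  if ("mean_distance" %in% metrics) {
    md <- mean_distance(network, sources, module)
    observed$mean_distance <- md$mean_distance
    observed$unreachable_pairs <- md$unreachable_pairs
  }
  if ("links" %in% metrics) observed$links <- links_metric(network, sources, module)
  if ("cov" %in% metrics) observed$cov <- cov_metric(network, sources, module)

  g <- if ("mean_distance" %in% metrics) as_igraph(network) else NULL
  mod_idx <- match(module, network$nodes)
  innb <- network$in_nbrs
  n <- length(network$nodes)

  set.seed(seed)
  null <- list(mean_distance = numeric(0), links = numeric(0),
               cov = numeric(0))
  null <- null[metrics]
  for (metric in metrics) null[[metric]] <- numeric(trials)
  for (t in seq_len(trials)) {
    draw <- sample(pool, length(sources))
    inset <- logical(n)
    inset[match(draw, network$nodes)] <- TRUE
    if ("links" %in% metrics || "cov" %in% metrics) {
      per_node <- vapply(mod_idx, function(u) sum(inset[innb[[u]]]), numeric(1))
      if ("links" %in% metrics) null$links[t] <- sum(per_node)
      if ("cov" %in% metrics) null$cov[t] <- mean(per_node > 0)
    }
    if ("mean_distance" %in% metrics) {
      d <- igraph::distances(g, v = draw, to = module, mode = "out")
      fin <- is.finite(d)
      null$mean_distance[t] <- if (any(fin)) mean(d[fin]) else Inf
    }
  }

  p <- list()
  if ("mean_distance" %in% metrics) {
    p$mean_distance <- mean(null$mean_distance <= observed$mean_distance)
  }
  if ("links" %in% metrics) p$links <- mean(null$links >= observed$links)
  if ("cov" %in% metrics) p$cov <- mean(null$cov >= observed$cov)

  structure(
    list(sources = sources, module = module, observed = observed,
         null = null, p_values = p, trials = as.integer(trials),
         seed = as.integer(seed)),
    class = "module_control_report"
  )
}

#' @export
print.module_control_report <- function(x, ...) {
  cat("<module_control_report> |sources| = ", length(x$sources),
      ", |module| = ", length(x$module), ", ", x$trials, " trials\n",
      sep = "")
  for (metric in names(x$p_values)) {
    cat(sprintf("  %-14s observed = %-8.4g p = %.4g\n", metric,
                x$observed[[metric]], x$p_values[[metric]]))
  }
  invisible(x)
}

#' Top-k node sets under standard centrality metrics
#'
#' Baseline selections for comparing against high criticality nodes:
#' closeness (outgoing distances), betweenness, PageRank (damping 0.85),
#' out-degree and total degree. Ties are broken deterministically by
#' node-identifier order.
#'
#' @param network a [directed_network()].
#' @param k set size, at most the number of nodes.
#' @return Named list of character vectors, one per centrality.
#' @export
centrality_baselines <- function(network, k) {
  stopifnot(inherits(network, "directed_network"),
            k >= 1, k <= length(network$nodes))
  g <- as_igraph(network)
  deg <- node_degrees(network)
  vals <- list(
    closeness = suppressWarnings(
      igraph::closeness(g, mode = "out"))[network$nodes],
    betweenness = igraph::betweenness(g, directed = TRUE)[network$nodes],
    page_rank = igraph::page_rank(g, damping = 0.85)$vector[network$nodes],
    out_degree = stats::setNames(deg$out_degree, deg$node_id),
    total_degree = stats::setNames(deg$in_degree + deg$out_degree,
                                   deg$node_id)
  )
  lapply(vals, function(v) {
    v[is.na(v)] <- -Inf   # closeness is NaN for nodes that reach nothing
    network$nodes[order(-v, network$nodes)][seq_len(k)]
  })
}
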