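#' Enumerate all minimum dominating sets by brute force
#'
#' Ground-truth oracle for small graphs: checks subsets in increasing
#' cardinality and returns every dominating set of the first feasible size.
#' No pruning is applied, so nothing can be dropped. Refuses networks larger
#' than `max_nodes` to prevent accidental exponential runs.
#'
#' @param network a [directed_network()].
#' @param max_nodes refusal cap on the node count (default 20).
#' @return List of character vectors, one per MDS, in lexicographic index
#'   order.
#' @examples
#' all_mds(make_fixture("directed_cycle_4"))
#' @export
all_mds <- function(network, max_nodes = 20) {
  stopifnot(inherits(network, "directed_network"))
  n <- length(network$nodes)
  if (n > max_nodes) {
    stop("network has ", n, " nodes; oracle refuses above ", max_nodes,
         " (exhaustive enumeration is exponential)")
  }
  innb <- network$in_nbrs
  dominates <- function(sel) {
    inset <- logical(n)
    inset[sel] <- TRUE
    for (u in seq_len(n)) {
      if (!inset[u] && !any(inset[innb[[u]]])) return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(n)) {
    combos <- utils::combn(n, k)
    ok <- apply(combos, 2L, dominates)
    if (any(ok)) {
      sols <- combos[, ok, drop = FALSE]
      return(lapply(seq_len(ncol(sols)),
                    function(j) network$nodes[sols[, j]]))
    }
  }
  stop("unreachable: the full node set always dominates")
}

#' Exact criticality from complete enumeration
#'
#' Evaluates the criticality definition directly on the complete MDS list
#' from [all_mds()].
#'
#' @inheritParams all_mds
#' @return Named numeric vector of exact scores.
#' @export
exact_criticality <- function(network, max_nodes = 20) {
  criticality_scores(all_mds(network, max_nodes), network$nodes)
}

#' Exact control categories from complete enumeration
#'
#' @inheritParams all_mds
#' @return Named character vector: critical (in all MDSs), redundant (in
#'   none), intermittent (otherwise).
#' @export
oracle_categories <- function(network, max_nodes = 20) {
  cr <- exact_criticality(network, max_nodes)
  stats::setNames(
    ifelse(cr == 1, "critical", ifelse(cr == 0, "redundant", "intermittent")),
    names(cr)
  )
}
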