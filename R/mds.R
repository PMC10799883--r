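#' Construct a node subset
#'
#' A subset of a network's node set together with its binary-vector view
#' (entry `i` is 1 iff node `i` of the network ordering belongs to the
#' subset). The binary view is what Hamming distances are computed on.
#'
#' @param members character vector of node identifiers.
#' @param network the [directed_network()] the subset lives on.
#' @return An object of class `node_subset`.
#' @export
node_subset <- function(members, network) {
  stopifnot(inherits(network, "directed_network"))
  members <- unique(as.character(members))
  extra <- setdiff(members, network$nodes)
  if (length(extra)) {
    stop("subset members not in network: ", paste(extra, collapse = ", "))
  }
  structure(list(members = members[order(match(members, network$nodes))],
                 universe = network$nodes),
            class = "node_subset")
}

#' @export
print.node_subset <- function(x, ...) {
  cat("<node_subset> {", paste(x$members, collapse = ", "), "} of ",
      length(x$universe), " nodes\n", sep = "")
  invisible(x)
}

#' Binary membership vector of a node subset
#'
#' @param x a [node_subset()].
#' @return Integer 0/1 vector named by node identifier, in network order.
#' @export
as_binary <- function(x) {
  stopifnot(inherits(x, "node_subset"))
  stats::setNames(as.integer(x$universe %in% x$members), x$universe)
}

#' Hamming distance between two node subsets
#'
#' Number of differing entries of the binary membership vectors; equals
#' `|A \\ B| + |B \\ A|`. Both subsets must be defined over the same network.
#'
#' @param a,b [node_subset()] objects over the same network.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(inherits(a, "node_subset"), inherits(b, "node_subset"))
  if (!identical(a$universe, b$universe)) {
    stop("subsets are defined over different networks")
  }
  length(setdiff(a$members, b$members)) + length(setdiff(b$members, a$members))
}

#' Compute one minimum dominating set
#'
#' Solves the domination ILP with no extra constraints. The result is a
#' dominating set of globally minimum cardinality; it is generally not
#' unique (see [compute_criticality()] for the full enumeration).
#'
#' @param network a [directed_network()].
#' @param config a [solver_config()].
#' @return A [node_subset()]; its size is `|MDS|`.
#' @examples
#' minimum_dominating_set(make_fixture("star_out_5"))
#' @export
minimum_dominating_set <- function(network, config = solver_config()) {
  res <- solve_ilp(network, ilp_spec(network), config)
  if (res$status != "optimal") stop("no dominating set found; this is a bug")
  node_subset(res$members, network)
}

#' Classify nodes into MDS control categories
#'
#' A node is *critical* when it belongs to every minimum dominating set,
#' *redundant* when it belongs to none, and *intermittent* otherwise. The
#' classification is derived directly from the definition by per-node
#' forcing: after the base solve (optimum `|MDS|`), a node in the seed MDS is
#' critical iff re-solving with `x_v = 0` is infeasible or exceeds `|MDS|`;
#' a node outside the seed is redundant iff re-solving with `x_v = 1`
#' exceeds `|MDS|`. (A node in the seed is in some MDS, hence never
#' redundant; a node outside it is not in all, hence never critical — so one
#' extra solve per node suffices.)
#'
#' @param network a [directed_network()].
#' @param config a [solver_config()].
#' @return An object of class `control_classification`: `mds_size`,
#'   `categories` (named character: critical / intermittent / redundant),
#'   `cmds`, `imds`, `rmds` (character vectors partitioning the node set)
#'   and `seed_mds` (a [node_subset()]).
#' @examples
#' classify_nodes(make_fixture("directed_cycle_4"))
#' @export
classify_nodes <- function(network, config = solver_config()) {
  stopifnot(inherits(network, "directed_network"))
  seed <- minimum_dominating_set(network, config)
  m <- length(seed$members)
  categories <- stats::setNames(character(length(network$nodes)),
                                network$nodes)
  for (v in network$nodes) {
    if (v %in% seed$members) {
      res <- solve_ilp(network, ilp_spec(network, forced_out = v), config)
      categories[[v]] <- if (res$status != "optimal" || res$objective > m)
        "critical" else "intermittent"
    } else {
      res <- solve_ilp(network, ilp_spec(network, forced_in = v), config)
      categories[[v]] <- if (res$objective > m) "redundant" else "intermittent"
    }
  }
  cls <- structure(
    list(mds_size = m,
         categories = categories,
         cmds = names(categories)[categories == "critical"],
         imds = names(categories)[categories == "intermittent"],
         rmds = names(categories)[categories == "redundant"],
         seed_mds = seed),
    class = "control_classification"
  )
  # invariants from the category definitions
  stopifnot(
    all(cls$cmds %in% seed$members),
    !any(cls$rmds %in% seed$members),
    length(cls$cmds) <= m,
    m <= length(cls$cmds) + length(cls$imds)
  )
  cls
}

#' @export
print.control_classification <- function(x, ...) {
  cat("<control_classification> |MDS| = ", x$mds_size,
      ": ", length(x$cmds), " critical, ", length(x$imds),
      " intermittent, ", length(x$rmds), " redundant\n", sep = "")
  invisible(x)
}
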