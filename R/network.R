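#' Construct a directed network
#'
#' The basic container of the package: an ordered set of node identifiers and
#' a set of directed edges between them. Node identifiers are opaque strings;
#' internal indexing follows insertion order (declared nodes first, then first
#' appearance in the edge list), and all user-facing output is keyed by
#' identifier so internal order never leaks.
#'
#' Self-loops are stripped with a warning: in the domination constraint a node
#' may always dominate itself, so a self-loop adds nothing and would
#' double-count. Duplicate edges are collapsed with a warning. When
#' `directed = FALSE` each undirected pair is expanded to both directions.
#'
#' @param edges two-column character matrix or data frame of (source, target)
#'   pairs; may have zero rows.
#' @param nodes optional character vector of node identifiers; lets isolated
#'   nodes be declared and fixes their position in the ordering.
#' @param directed logical; `FALSE` expands every edge to both directions.
#' @return An object of class `directed_network` with elements `nodes`
#'   (character), `edges` (two-column character matrix), `directed`, and
#'   integer adjacency indexes `in_nbrs`/`out_nbrs`.
#' @examples
#' net <- directed_network(rbind(c("a", "b"), c("b", "c")))
#' net
#' @export
directed_network <- function(edges, nodes = NULL, directed = TRUE) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.character(edges)) storage.mode(edges) <- "character"
  if (ncol(edges) < 2L) stop("`edges` must have two columns (source, target)")
  edges <- edges[, 1:2, drop = FALSE]

  if (!directed && nrow(edges) > 0L) {
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    dup <- duplicated(paste0(lo, "\r", hi))
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) collapsed")
      edges <- edges[!dup, , drop = FALSE]
    }
    edges <- rbind(edges, edges[, 2:1, drop = FALSE])
  }

  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) stripped (a node always dominates itself)")
  }
  # node ordering is fixed before any row is dropped so declared loops still
  # register their endpoint
  all_ids <- c(nodes, as.vector(t(edges)))
  node_ids <- unique(all_ids)
  if (length(node_ids) == 0L) stop("empty network: no nodes declared and no edges")
  edges <- edges[!loops, , drop = FALSE]

  key <- paste0(edges[, 1L], "\r", edges[, 2L])
  dup <- duplicated(key)
  if (any(dup)) {
    if (directed) warning(sum(dup), " duplicate edge(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  dimnames(edges) <- list(NULL, c("source", "target"))

  idx <- stats::setNames(seq_along(node_ids), node_ids)
  n <- length(node_ids)
  in_nbrs <- vector("list", n)
  out_nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    in_nbrs[[i]] <- integer(0)
    out_nbrs[[i]] <- integer(0)
  }
  if (nrow(edges) > 0L) {
    src <- unname(idx[edges[, 1L]])
    tgt <- unname(idx[edges[, 2L]])
    in_split <- split(src, tgt)
    for (nm in names(in_split)) in_nbrs[[as.integer(nm)]] <- sort(in_split[[nm]])
    out_split <- split(tgt, src)
    for (nm in names(out_split)) out_nbrs[[as.integer(nm)]] <- sort(out_split[[nm]])
  }

  structure(
    list(nodes = node_ids, edges = edges, directed = directed,
         in_nbrs = in_nbrs, out_nbrs = out_nbrs),
    class = "directed_network"
  )
}

#' @export
print.directed_network <- function(x, ...) {
  cat("<directed_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed edges\n", sep = "")
  invisible(x)
}

#' In- and out-degrees of every node
#'
#' @param network a [directed_network()].
#' @return data frame with columns `node_id`, `in_degree`, `out_degree`.
#' @export
node_degrees <- function(network) {
  stopifnot(inherits(network, "directed_network"))
  data.frame(
    node_id = network$nodes,
    in_degree = vapply(network$in_nbrs, length, integer(1)),
    out_degree = vapply(network$out_nbrs, length, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Read a directed network from a plain-text edge list
#'
#' One edge per line as two whitespace- or TAB-separated tokens
#' `source target`; extra tokens are ignored. Lines starting with `#` are
#' comments. A single-token line declares an isolated node. With
#' `directed = FALSE` every pair is expanded to both directions.
#'
#' @param path path to the edge-list file.
#' @param directed logical; treat pairs as directed edges (default) or expand
#'   to both directions.
#' @return A [directed_network()].
#' @export
read_edge_list <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  singles <- character(0)
  src <- character(0)
  tgt <- character(0)
  for (i in which(keep)) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(toks) == 0L) {
      stop("malformed line ", i, " in ", path)
    } else if (length(toks) == 1L) {
      singles <- c(singles, toks)
    } else {
      src <- c(src, toks[[1]])
      tgt <- c(tgt, toks[[2]])
    }
  }
  if (length(singles) == 0L && length(src) == 0L) {
    stop("empty graph in ", path, ": no nodes or edges")
  }
  directed_network(cbind(src, tgt), nodes = singles, directed = directed)
}

#' Write a network as a plain-text edge list
#'
#' Inverse of [read_edge_list()]: isolated nodes are written as single-token
#' lines, every edge as `source<TAB>target`. Reading the file back yields an
#' identical node and edge set.
#'
#' @param network a [directed_network()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "directed_network"))
  touched <- unique(as.vector(network$edges))
  isolated <- setdiff(network$nodes, touched)
  lines <- c(isolated,
             if (nrow(network$edges) > 0L)
               paste(network$edges[, 1L], network$edges[, 2L], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed network from a GraphML file
#'
#' Convenience reader; only node identifiers and directed edges are used.
#'
#' @param path path to a GraphML file.
#' @return A [directed_network()].
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(g, "name")
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(ids[el[, 1L]], ids[el[, 2L]])
  directed_network(edges, nodes = ids, directed = igraph::is_directed(g))
}

#' Convert a network to an igraph object
#'
#' @param network a [directed_network()].
#' @return An [igraph::graph] with vertex names equal to the node identifiers.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "directed_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE)
  )
}

#' Read node annotations from a two-column TSV
#'
#' Each line maps one node identifier to one label (`node_id<TAB>label`).
#' Members may include identifiers absent from any given network; statistics
#' intersect them with the network's node set first.
#'
#' @param path path to the annotation file.
#' @return Named list of [annotation_set()] objects, one per distinct label.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("node_id", "label"),
                           colClasses = "character", comment.char = "#")
  if (nrow(tab) == 0L) stop("no annotations in ", path)
  by_label <- split(tab$node_id, tab$label)
  stats::setNames(
    lapply(names(by_label), function(l) annotation_set(l, by_label[[l]])),
    names(by_label)
  )
}

#' Construct an annotation set
#'
#' @param label label of the set (e.g. a disease, a neuron class, a
#'   post-translational modification).
#' @param members character vector of node identifiers carrying the label.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(label, members) {
  stopifnot(is.character(label), length(label) == 1L)
  structure(list(label = label, members = unique(as.character(members))),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> '", x$label, "': ", length(x$members), " members\n",
      sep = "")
  invisible(x)
}

#' Write the per-node criticality table
#'
#' Writes a TSV with columns `node_id`, `category` (critical / high / low /
#' redundant), `criticality` (6 decimal places), `in_degree`, `out_degree`.
#'
#' @param result a `criticality_result` from [compute_criticality()].
#' @param path output path.
#' @return Invisibly, the written data frame.
#' @export
write_node_table <- function(result, path) {
  stopifnot(inherits(result, "criticality_result"))
  tab <- as.data.frame(result)
  out <- tab
  out$criticality <- sprintf("%.6f", tab$criticality)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Per-node table of a criticality result
#'
#' @param x a `criticality_result`.
#' @param ... unused.
#' @return Data frame with columns `node_id`, `category`, `criticality`,
#'   `in_degree`, `out_degree`, in network node order.
#' @export
as.data.frame.criticality_result <- function(x, ...) {
  deg <- node_degrees(x$network)
  data.frame(
    node_id = x$network$nodes,
    category = unname(x$categories[x$network$nodes]),
    criticality = unname(x$scores[x$network$nodes]),
    in_degree = deg$in_degree,
    out_degree = deg$out_degree,
    stringsAsFactors = FALSE
  )
}

#' Built-in fixture networks
#'
#' `star_out_<k>` is a directed out-star (one center with edges to `k`
#' leaves); `directed_cycle_<n>` is a directed cycle on `n` nodes; `"fig1"`
#' is the 10-node worked-example network shipped with the package
#' (`inst/extdata/fig1_edges.tsv`): one critical node, six intermittent nodes
#' and three redundant nodes, with exactly four minimum dominating sets of
#' size four.
#'
#' @param name fixture identifier: `"star_out_<k>"`, `"directed_cycle_<n>"`
#'   or `"fig1"`.
#' @return A [directed_network()].
#' @examples
#' make_fixture("star_out_5")
#' make_fixture("directed_cycle_4")
#' @export
make_fixture <- function(name) {
  if (grepl("^star_out_[0-9]+$", name)) {
    k <- as.integer(sub("^star_out_", "", name))
    if (k < 1L) stop("star needs at least one leaf")
    leaves <- paste0("leaf", seq_len(k))
    return(directed_network(cbind("center", leaves)))
  }
  if (grepl("^directed_cycle_[0-9]+$", name)) {
    n <- as.integer(sub("^directed_cycle_", "", name))
    if (n < 2L) stop("cycle needs at least two nodes")
    ids <- paste0("v", seq_len(n))
    return(directed_network(cbind(ids, ids[c(2:n, 1L)])))
  }
  if (name == "fig1") {
    path <- system.file("extdata", "fig1_edges.tsv", package = "mdscrit",
                        mustWork = TRUE)
    return(read_edge_list(path))
  }
  stop("unknown fixture: '", name, "'")
}
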