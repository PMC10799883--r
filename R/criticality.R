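#' Initial Hamming bound for the enumeration ladder
#'
#' The enumeration starts at the most constrained level: writing `h` for the
#' number of nodes swapped between two minimum dominating sets, the Hamming
#' distance between their binary vectors is `2h`, and `h` is bounded above by
#' `n = min(|IMDS| + |CMDS| - |MDS|, |MDS| - |CMDS|)`. The ILP-side bound is
#' `K = 2n - |MDS|` (a solution with overlap `a` against a reference set has
#' constraint value `|MDS| - 2a`, so `K` at level `h` forces at least `h`
#' swapped nodes). When there are no intermittent nodes the MDS is unique and
#' `K = -|MDS|`, below the ladder floor, so the loop is never entered.
#'
#' @param classification a `control_classification` from [classify_nodes()].
#' @return Integer `K`.
#' @export
initial_k <- function(classification) {
  stopifnot(inherits(classification, "control_classification"))
  m <- classification$mds_size
  nI <- length(classification$imds)
  nC <- length(classification$cmds)
  if (nI == 0L) return(-m)
  h_max <- min(nI + nC - m, m - nC)
  2L * h_max - m
}

#' Criticality scores from an enumerated solution list
#'
#' The criticality of a node is the fraction of enumerated minimum
#' dominating sets that contain it.
#'
#' @param solutions non-empty list of character vectors (or [node_subset()]
#'   objects), each one MDS.
#' @param nodes character vector of all node identifiers to score.
#' @return Named numeric vector in `[0, 1]`.
#' @export
criticality_scores <- function(solutions, nodes) {
  if (length(solutions) == 0L) stop("empty solution list")
  members <- lapply(solutions, function(s) {
    if (inherits(s, "node_subset")) s$members else as.character(s)
  })
  counts <- table(factor(unlist(members), levels = nodes))
  stats::setNames(as.numeric(counts) / length(members), nodes)
}

#' Root-mean-square criticality change between rounds
#'
#' Only intermittent nodes enter the average: critical and redundant nodes
#' hold scores 1 and 0 at every round, so they carry no information about
#' convergence.
#'
#' @param prev_scores,curr_scores named score vectors covering `imds`.
#' @param imds character vector of intermittent node identifiers; must be
#'   non-empty.
#' @return Non-negative scalar.
#' @export
dcr <- function(prev_scores, curr_scores, imds) {
  if (length(imds) == 0L) stop("no intermittent nodes: dCR is undefined")
  stopifnot(all(imds %in% names(prev_scores)),
            all(imds %in% names(curr_scores)))
  sqrt(mean((curr_scores[imds] - prev_scores[imds])^2))
}

#' Enumerate minimum dominating sets and compute node criticality
#'
#' Runs the Hamming-ladder enumeration. After classifying every node
#' (critical / intermittent / redundant), critical nodes are fixed in and
#' redundant nodes fixed out of all subsequent solves. Starting from the
#' maximum Hamming bound `K` (see [initial_k()]), each round repeatedly
#' solves the domination ILP at cardinality `|MDS|` under the constraint
#' that every new solution must lie at Hamming distance at least the current
#' level from *every* previously found solution, until the constrained
#' program becomes infeasible. Scores are then recomputed over all solutions
#' found so far; from the second round on, the root-mean-square score change
#' ([dcr()]) is compared against `theta` and the run stops when it drops
#' below `theta` or when `K` reaches the floor `2 - |MDS|` (at which point
#' any not-yet-found solution would be admissible, so the enumeration is
#' complete). Otherwise `K` decreases by 2 and the next round begins.
#'
#' With `theta = 0` the ladder always runs to the floor and the returned
#' solution list is the complete set of minimum dominating sets; scores are
#' then exact. With `theta > 0` the result is an approximation whose
#' per-round trace is returned for auditing.
#'
#' @param network a [directed_network()].
#' @param theta convergence threshold on [dcr()]; `0` forces exhaustive
#'   enumeration (default `0.01`).
#' @param config a [solver_config()].
#' @return An object of class `criticality_result`: `scores` (named numeric),
#'   `categories` (critical / high / low / redundant, from
#'   [classify_by_score()]), `solutions` (list of character vectors in
#'   discovery order), `rounds` (data frame with columns `k`,
#'   `solutions_found`, `dcr`), `classification`, `theta`, `converged_by`
#'   (`"dcr_threshold"` or `"k_floor"`) and `network`.
#' @examples
#' res <- compute_criticality(make_fixture("directed_cycle_4"), theta = 0)
#' res$scores
#' @export
compute_criticality <- function(network, theta = 0.01,
                                config = solver_config()) {
  stopifnot(inherits(network, "directed_network"),
            is.numeric(theta), length(theta) == 1L, theta >= 0)
  cls <- classify_nodes(network, config)
  m <- cls$mds_size
  nodes <- network$nodes

  if (length(cls$imds) == 0L) {
    # unique MDS: the score vector is its indicator
    scores <- criticality_scores(list(cls$seed_mds$members), nodes)
    return(new_criticality_result(
      scores, list(cls$seed_mds$members),
      data.frame(k = integer(0), solutions_found = integer(0),
                 dcr = numeric(0)),
      cls, theta, "k_floor", network))
  }

  solutions <- list(cls$seed_mds$members)
  k <- initial_k(cls)
  k_floor <- 2L - m
  prev_scores <- criticality_scores(solutions, nodes)
  rounds <- list()
  converged_by <- NULL
  round_i <- 0L

  repeat {
    round_i <- round_i + 1L
    found <- 0L
    repeat {
      spec <- ilp_spec(
        network,
        forced_in = cls$cmds,
        forced_out = cls$rmds,
        hamming = lapply(solutions, function(s) list(members = s, k = k)),
        cardinality_equals = m
      )
      res <- tryCatch(solve_ilp(network, spec, config),
                      mdscrit_timeout = function(e) {
                        stop(partial_trace_error(e, rounds, solutions, k))
                      })
      if (res$status != "optimal") break
      stopifnot(length(res$members) == m)
      solutions[[length(solutions) + 1L]] <- res$members
      found <- found + 1L
    }
    curr_scores <- criticality_scores(solutions, nodes)
    d <- if (round_i >= 2L) dcr(prev_scores, curr_scores, cls$imds)
         else NA_real_
    rounds[[round_i]] <- data.frame(k = k, solutions_found = found, dcr = d)
    if (!is.na(d) && d < theta) { converged_by <- "dcr_threshold"; break }
    if (k <= k_floor) { converged_by <- "k_floor"; break }
    prev_scores <- curr_scores
    k <- k - 2L
  }

  scores <- criticality_scores(solutions, nodes)
  # critical and redundant nodes must score 1 and 0 at any theta
  stopifnot(all(scores[cls$cmds] == 1), all(scores[cls$rmds] == 0),
            !any(duplicated(vapply(solutions, function(s)
      paste(sort(s), collapse = "\r"), character(1)))))
  new_criticality_result(scores, solutions, do.call(rbind, rounds), cls,
                         theta, converged_by, network)
}

partial_trace_error <- function(e, rounds, solutions, k) {
  trace <- if (length(rounds)) do.call(rbind, rounds) else NULL
  structure(
    class = c("mdscrit_timeout", "error", "condition"),
    list(message = paste0(conditionMessage(e),
                          sprintf(" [aborted at K = %d after %d solution(s)]",
                                  k, length(solutions))),
         call = NULL, rounds = trace, solutions = solutions, k = k)
  )
}

new_criticality_result <- function(scores, solutions, rounds, classification,
                                   theta, converged_by, network) {
  structure(
    list(scores = scores,
         categories = classify_by_score(scores),
         solutions = solutions,
         rounds = rounds,
         classification = classification,
         theta = theta,
         converged_by = converged_by,
         network = network),
    class = "criticality_result"
  )
}

#' @export
print.criticality_result <- function(x, ...) {
  cat("<criticality_result> |MDS| = ", x$classification$mds_size, ", ",
      length(x$solutions), " solution(s) enumerated over ",
      nrow(x$rounds), " round(s) (theta = ", format(x$theta),
      ", stopped by ", x$converged_by, ")\n", sep = "")
  tab <- table(factor(x$categories,
                      levels = c("critical", "high", "low", "redundant")))
  cat("  categories: ", paste(names(tab), tab, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Classify nodes by criticality score
#'
#' Score 1 is *critical*, score 0 *redundant*; intermediate scores are
#' *high* criticality when strictly above the threshold and *low* otherwise
#' (a score exactly at the threshold is classified low, since high is
#' defined as strictly above).
#'
#' @param scores named numeric vector of scores in `[0, 1]`.
#' @param threshold high/low cut in `(0, 1)`; default 0.5.
#' @return Named character vector with values critical / high / low /
#'   redundant.
#' @export
classify_by_score <- function(scores, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  out <- ifelse(scores == 1, "critical",
         ifelse(scores == 0, "redundant",
         ifelse(scores > threshold, "high", "low")))
  stats::setNames(out, names(scores))
}
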