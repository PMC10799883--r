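#' Solver configuration
#'
#' The solver is a deterministic exact branch-and-bound: variables are
#' explored in node insertion order, so reruns enumerate identically. The
#' only tunable is the per-solve time limit; on timeout the solve aborts with
#' a condition of class `mdscrit_timeout` carrying the best objective bound
#' found so far.
#'
#' @param time_limit per-solve wall-clock limit in seconds (default 600).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(time_limit = 600) {
  stopifnot(is.numeric(time_limit), time_limit > 0)
  structure(list(time_limit = time_limit), class = "solver_config")
}

#' Specify a domination integer linear program
#'
#' Binary variable `x_v` per node; objective `minimize sum x_v`; one
#' domination constraint per node `u`: `x_u + sum_{(v,u) in E} x_v >= 1`.
#' Optional extras: nodes forced in (`x_v = 1`) or out (`x_v = 0`), Hamming
#' constraints `-sum_{v in S} x_v + sum_{v notin S} x_v >= K` relative to
#' reference sets `S`, and an exact cardinality `sum x_v = m`.
#'
#' @param network a [directed_network()].
#' @param forced_in,forced_out character vectors of node identifiers with
#'   `x_v` fixed to 1 / 0; must be disjoint.
#' @param hamming list of `list(members = <character>, k = <integer>)`
#'   Hamming constraints.
#' @param cardinality_equals optional integer: require `sum x_v` equal to it.
#' @return An object of class `ilp_spec`.
#' @export
ilp_spec <- function(network, forced_in = character(0),
                     forced_out = character(0), hamming = list(),
                     cardinality_equals = NULL) {
  stopifnot(inherits(network, "directed_network"))
  forced_in <- unique(as.character(forced_in))
  forced_out <- unique(as.character(forced_out))
  unknown <- setdiff(c(forced_in, forced_out), network$nodes)
  if (length(unknown)) {
    stop("constraint references undeclared node(s): ",
         paste(unknown, collapse = ", "))
  }
  if (length(intersect(forced_in, forced_out))) {
    stop("forced_in and forced_out overlap")
  }
  for (h in hamming) {
    if (!is.list(h) || is.null(h$members) || is.null(h$k)) {
      stop("each hamming constraint needs `members` and `k`")
    }
    if (length(setdiff(h$members, network$nodes))) {
      stop("hamming constraint references undeclared node(s)")
    }
  }
  if (!is.null(cardinality_equals)) {
    cardinality_equals <- as.integer(cardinality_equals)
    stopifnot(cardinality_equals >= 0L)
  }
  structure(
    list(network = network, forced_in = forced_in, forced_out = forced_out,
         hamming = hamming, cardinality_equals = cardinality_equals),
    class = "ilp_spec"
  )
}

#' Check that a node set dominates a network
#'
#' A set dominates when every node either belongs to it or has at least one
#' incoming edge from a member. Used to re-validate every solver result in
#' plain code.
#'
#' @param network a [directed_network()].
#' @param members character vector of node identifiers.
#' @return `TRUE` or `FALSE`.
#' @export
verify_domination <- function(network, members) {
  stopifnot(inherits(network, "directed_network"))
  n <- length(network$nodes)
  inset <- network$nodes %in% members
  for (u in seq_len(n)) {
    if (!inset[u] && !any(inset[network$in_nbrs[[u]]])) return(FALSE)
  }
  TRUE
}

# Exact depth-first branch-and-bound for the domination ILP.
#
# Branching follows the classic cover scheme: pick the undominated node with
# the fewest admissible dominators and branch over them, excluding earlier
# choices in later branches so no assignment is visited twice. When all nodes
# are dominated but a Hamming or cardinality constraint is still open, binary
# branching on a remaining free variable completes the search. Lower bound:
# current size + ceiling(#undominated / best single-node coverage).
#
# Returns list(status = "optimal"|"infeasible", members, objective, bound).
solve_ilp_raw <- function(network, spec, config) {
  n <- length(network$nodes)
  idx <- stats::setNames(seq_len(n), network$nodes)
  outnb <- network$out_nbrs
  dominators <- lapply(seq_len(n), function(u) sort(c(u, network$in_nbrs[[u]])))
  m <- spec$cardinality_equals
  has_m <- !is.null(m)

  nh <- length(spec$hamming)
  inS <- lapply(spec$hamming, function(h) {
    v <- logical(n); v[idx[unique(h$members)]] <- TRUE; v
  })
  Kh <- vapply(spec$hamming, function(h) as.integer(h$k), integer(1))

  status <- integer(n)        # 0 free, 1 in, -1 out
  dom_cnt <- integer(n)       # number of selected dominators covering u
  count <- 0L
  cur <- integer(nh)          # Hamming LHS over decided variables
  pot <- vapply(seq_len(nh), function(j) sum(!inS[[j]]), integer(1))

  best_obj <- Inf
  best_sol <- NULL
  done <- FALSE
  timed_out <- FALSE
  deadline <- Sys.time() + config$time_limit

  set_in <- function(v) {
    status[v] <<- 1L
    count <<- count + 1L
    cov <- c(v, outnb[[v]])
    dom_cnt[cov] <<- dom_cnt[cov] + 1L
    for (j in seq_len(nh)) {
      if (inS[[j]][v]) cur[j] <<- cur[j] - 1L
      else { cur[j] <<- cur[j] + 1L; pot[j] <<- pot[j] - 1L }
    }
  }
  unset_in <- function(v) {
    status[v] <<- 0L
    count <<- count - 1L
    cov <- c(v, outnb[[v]])
    dom_cnt[cov] <<- dom_cnt[cov] - 1L
    for (j in seq_len(nh)) {
      if (inS[[j]][v]) cur[j] <<- cur[j] + 1L
      else { cur[j] <<- cur[j] - 1L; pot[j] <<- pot[j] + 1L }
    }
  }
  set_out <- function(v) {
    status[v] <<- -1L
    for (j in seq_len(nh)) if (!inS[[j]][v]) pot[j] <<- pot[j] - 1L
  }
  unset_out <- function(v) {
    status[v] <<- 0L
    for (j in seq_len(nh)) if (!inS[[j]][v]) pot[j] <<- pot[j] + 1L
  }

  search <- function() {
    if (done || timed_out) return()
    if (Sys.time() > deadline) { timed_out <<- TRUE; return() }
    if (has_m && count > m) return()
    if (nh > 0L) {
      slots <- if (has_m) m - count else n
      for (j in seq_len(nh)) {
        if (cur[j] + min(pot[j], slots) < Kh[j]) return()
      }
    }
    undom <- which(dom_cnt == 0L)
    if (length(undom) == 0L) {
      ham_ok <- nh == 0L || all(cur >= Kh)
      card_ok <- !has_m || count == m
      if (ham_ok && card_ok) {
        if (count < best_obj) {
          best_obj <<- count
          best_sol <<- which(status == 1L)
          if (has_m) done <<- TRUE    # any solution at fixed cardinality suffices
        }
        return()
      }
      if (has_m && count == m) return()   # no slack left to repair constraints
      freev <- which(status == 0L)
      if (length(freev) == 0L) return()
      if (!has_m && count + 1L >= best_obj) return()
      pool <- freev
      viol <- which(cur < Kh)
      if (length(viol)) {
        pool <- freev[!inS[[viol[1L]]][freev]]
        if (length(pool) == 0L) return()
      }
      v <- pool[1L]
      set_in(v); search(); unset_in(v)
      set_out(v); search(); unset_out(v)
      return()
    }
    # cover branching on the least-flexible undominated node
    covcnt <- integer(n)
    best_u <- 0L
    best_len <- .Machine$integer.max
    best_cands <- NULL
    for (u in undom) {
      cands <- dominators[[u]]
      cands <- cands[status[cands] == 0L]
      if (length(cands) == 0L) return()
      covcnt[cands] <- covcnt[cands] + 1L
      if (length(cands) < best_len) {
        best_len <- length(cands); best_u <- u; best_cands <- cands
      }
    }
    need <- ceiling(length(undom) / max(covcnt))
    if (count + need >= best_obj) return()
    if (has_m && count + need > m) return()
    placed <- 0L
    for (d in best_cands) {
      set_in(d); search(); unset_in(d)
      set_out(d); placed <- placed + 1L
      if (done || timed_out) break
    }
    for (d in best_cands[seq_len(placed)]) unset_out(d)
  }

  for (v in idx[spec$forced_in]) set_in(v)
  for (v in idx[spec$forced_out]) set_out(v)
  search()

  if (timed_out) {
    cond <- structure(
      class = c("mdscrit_timeout", "error", "condition"),
      list(message = sprintf("ILP solve exceeded %gs (best bound: %s)",
                             config$time_limit,
                             if (is.finite(best_obj)) best_obj else "none"),
           call = sys.call(-1), best_bound = best_obj)
    )
    stop(cond)
  }
  if (is.null(best_sol)) {
    return(list(status = "infeasible", members = NULL, objective = NA_real_))
  }
  list(status = "optimal", members = network$nodes[best_sol],
       objective = best_obj)
}

#' Solve a domination ILP
#'
#' Exact deterministic branch-and-bound over the binary node variables.
#' Every returned set is re-validated in plain code against the domination,
#' forcing, Hamming and cardinality constraints; a violation is a hard error.
#'
#' @param network a [directed_network()].
#' @param spec an [ilp_spec()].
#' @param config a [solver_config()].
#' @return `list(status, members, objective)`: `status` is `"optimal"` with
#'   `members` a character vector and `objective` its size, or
#'   `"infeasible"` with `members = NULL`.
#' @examples
#' net <- make_fixture("directed_cycle_4")
#' solve_ilp(net, ilp_spec(net))
#' @export
solve_ilp <- function(network, spec, config = solver_config()) {
  stopifnot(inherits(spec, "ilp_spec"), inherits(config, "solver_config"))
  res <- solve_ilp_raw(network, spec, config)
  if (res$status == "optimal") {
    if (!verify_domination(network, res$members)) {
      stop("solver returned a non-dominating set; this is a bug")
    }
    if (length(setdiff(spec$forced_in, res$members)) ||
        length(intersect(spec$forced_out, res$members))) {
      stop("solver violated a forcing constraint; this is a bug")
    }
    if (!is.null(spec$cardinality_equals) &&
        length(res$members) != spec$cardinality_equals) {
      stop("solver violated the cardinality constraint; this is a bug")
    }
    for (h in spec$hamming) {
      # LHS = (#members outside S) - (#members inside S)
      lhs <- sum(!(res$members %in% h$members)) - sum(res$members %in% h$members)
      if (lhs < h$k) stop("solver violated a Hamming constraint; this is a bug")
    }
  }
  res
}
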