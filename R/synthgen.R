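#' Configuration for the scale-free generator
#'
#' Defaults follow the scaling-study conditions used throughout the package:
#' power-law degree exponent 2.5 and mean in/out degree 3 (4 being the other
#' value of interest).
#'
#' @param n_nodes number of nodes (at least 10).
#' @param gamma power-law exponent of the in- and out-degree distributions;
#'   must exceed 2 so the mean is finite in the infinite-size limit.
#' @param mean_degree target mean in-degree (= mean out-degree), at least 1.
#' @param seed integer seed; generation is deterministic under a fixed seed.
#' @param degree_correlation in `[0, 1]`: probability that a node's
#'   out-degree is copied from its in-degree instead of drawn independently
#'   (0, the default, samples the two sequences independently).
#' @param max_rejects how many times the whole graph may be redrawn before
#'   giving up on meeting the realized-mean tolerance.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_nodes, gamma = 2.5, mean_degree = 3, seed = 1L,
                         degree_correlation = 0, max_rejects = 100L) {
  stopifnot(n_nodes >= 10, gamma > 2, mean_degree >= 1, max_rejects >= 1,
            degree_correlation >= 0, degree_correlation <= 1)
  structure(list(n_nodes = as.integer(n_nodes), gamma = gamma,
                 mean_degree = mean_degree, seed = as.integer(seed),
                 degree_correlation = degree_correlation,
                 max_rejects = as.integer(max_rejects)),
            class = "synth_config")
}

# Discrete power law on 1..k_max with an exact tail: P(k) proportional to
# k^(-gamma) for k >= 2, while the weight at k = 1 is a free parameter
# solved so the expectation equals the target mean. This keeps the tail
# exponent exactly gamma (a global shift would bend the measurable range)
# and makes the mean tunable between 1 and the mean of the k >= 2 law.
powerlaw_probs <- function(k_max, gamma, target_mean) {
  ks <- 1:k_max
  tail_w <- ks^(-gamma)
  mean_at <- function(log_w1) {
    w <- tail_w
    w[1] <- exp(log_w1)
    sum(ks * w) / sum(w) - target_mean
  }
  lo <- mean_at(25)    # almost all mass at k = 1: mean near 1
  hi <- mean_at(-25)   # no extra mass at k = 1: mean of the k >= 2 law
  if (lo > 0 || hi < 0) {
    stop("target mean ", target_mean, " unreachable with gamma = ", gamma,
         " and k_max = ", k_max)
  }
  log_w1 <- stats::uniroot(mean_at, c(-25, 25), tol = 1e-12)$root
  w <- tail_w
  w[1] <- exp(log_w1)
  w / sum(w)
}

#' Generate a scale-free directed network
#'
#' Directed configuration model: in- and out-degree sequences are sampled
#' independently per node from a truncated power law with exponent `gamma`
#' on `1..k_max` (`k_max = round(sqrt(n * mean_degree))`; the probability at
#' degree 1 is adjusted so the expected degree equals `mean_degree`, keeping
#' the tail exactly proportional to `k^-gamma`), the two stub multisets are
#' balanced by incrementing random nodes on the smaller side, and stubs are
#' paired uniformly at random. Self-loops and duplicate
#' edges are dropped, and the whole graph is redrawn (up to `max_rejects`
#' times) until the realized mean in-degree lies within 10% of the target.
#'
#' @param config a [synth_config()].
#' @return A [directed_network()] with attribute `synth` recording the
#'   configuration and the realized mean in-degree.
#' @examples
#' net <- scale_free_directed(synth_config(100, seed = 7))
#' @export
scale_free_directed <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_nodes
  k_max <- max(2L, round(sqrt(n * config$mean_degree)))
  probs <- powerlaw_probs(k_max, config$gamma, config$mean_degree)
  nodes <- paste0("n", seq_len(n))
  set.seed(config$seed)

  for (attempt in seq_len(config$max_rejects)) {
    k_in <- sample(1:k_max, n, replace = TRUE, prob = probs)
    k_out <- sample(1:k_max, n, replace = TRUE, prob = probs)
    if (config$degree_correlation > 0) {
      copy <- stats::runif(n) < config$degree_correlation
      k_out[copy] <- k_in[copy]
    }
    # balance the stub counts without disturbing either distribution much
    while (sum(k_in) != sum(k_out)) {
      if (sum(k_in) < sum(k_out)) {
        i <- sample.int(n, 1L)
        if (k_in[i] < k_max) k_in[i] <- k_in[i] + 1L
      } else {
        i <- sample.int(n, 1L)
        if (k_out[i] < k_max) k_out[i] <- k_out[i] + 1L
      }
    }
    src <- rep(seq_len(n), k_out)
    tgt <- rep(seq_len(n), k_in)
    if (length(src) == 0L) next
    tgt <- sample(tgt)
    keep <- src != tgt
    key <- paste0(src, "\r", tgt)
    keep <- keep & !duplicated(key)
    realized <- sum(keep) / n
    if (abs(realized - config$mean_degree) <= 0.1 * config$mean_degree) {
      net <- suppressWarnings(directed_network(
        cbind(nodes[src[keep]], nodes[tgt[keep]]), nodes = nodes))
      attr(net, "synth") <- list(config = config, attempts = attempt,
                                 realized_mean_in_degree = realized)
      return(net)
    }
  }
  stop("rejection budget exhausted: try a larger network or mean degree")
}

#' Planted fixtures with known criticality
#'
#' Builds graphs whose minimum dominating sets factorize over disjoint
#' components, so the exact criticality of every node (and the total number
#' of MDS solutions, the product over components) is known in closed form
#' and returned alongside the network. Kinds:
#'
#' * `"disjoint_components"` — `params$components`: character vector of
#'   [make_fixture()] names; nodes are prefixed `c<i>_`. Expected scores are
#'   computed per component by the brute-force oracle, independent of the
#'   ladder enumeration.
#' * `"star_forest"` — `params$leaf_counts`: integer vector; every center
#'   scores 1, every leaf 0, one solution in total.
#' * `"cycle_union"` — `params$lengths`: even cycle lengths; an even
#'   directed cycle has exactly the two alternating MDSs, so every node
#'   scores 0.5 and the union of `k` cycles has `2^k` solutions.
#'
#' @param kind one of `"disjoint_components"`, `"star_forest"`,
#'   `"cycle_union"`.
#' @param params named list of kind parameters (see above).
#' @return `list(network, expected_cr, n_solutions)`.
#' @examples
#' fx <- planted_fixture("cycle_union", list(lengths = c(4, 4)))
#' fx$n_solutions
#' @export
planted_fixture <- function(kind, params = list()) {
  switch(kind,
    disjoint_components = {
      comps <- params$components
      if (is.null(comps) || length(comps) == 0L) {
        stop("params$components must name at least one fixture")
      }
      nets <- lapply(comps, make_fixture)
      pieces <- Map(function(net, i) {
        pref <- function(x) paste0("c", i, "_", x)
        list(nodes = pref(net$nodes),
             edges = cbind(pref(net$edges[, 1L]), pref(net$edges[, 2L])),
             cr = stats::setNames(exact_criticality(net), pref(net$nodes)),
             n_sol = length(all_mds(net)))
      }, nets, seq_along(nets))
      network <- directed_network(
        do.call(rbind, lapply(pieces, `[[`, "edges")),
        nodes = unlist(lapply(pieces, `[[`, "nodes"))
      )
      list(network = network,
           expected_cr = unlist(lapply(pieces, `[[`, "cr")),
           n_solutions = prod(vapply(pieces, `[[`, numeric(1), "n_sol")))
    },
    star_forest = {
      sizes <- params$leaf_counts
      if (is.null(sizes) || any(sizes < 1)) {
        stop("params$leaf_counts must be positive integers")
      }
      names <- paste0("star_out_", sizes)
      fx <- planted_fixture("disjoint_components", list(components = names))
      fx
    },
    cycle_union = {
      lens <- params$lengths
      if (is.null(lens) || any(lens < 4) || any(lens %% 2 != 0)) {
        stop("params$lengths must be even integers >= 4 (odd cycles have no closed-form solution count)")
      }
      names <- paste0("directed_cycle_", lens)
      nets <- lapply(names, make_fixture)
      pieces <- Map(function(net, i) {
        pref <- function(x) paste0("c", i, "_", x)
        list(nodes = pref(net$nodes),
             edges = cbind(pref(net$edges[, 1L]), pref(net$edges[, 2L])))
      }, nets, seq_along(nets))
      network <- directed_network(
        do.call(rbind, lapply(pieces, `[[`, "edges")),
        nodes = unlist(lapply(pieces, `[[`, "nodes"))
      )
      list(network = network,
           expected_cr = stats::setNames(rep(0.5, length(network$nodes)),
                                         network$nodes),
           n_solutions = 2^length(lens))
    },
    stop("unknown fixture kind: '", kind, "'")
  )
}
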