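#' Two-tailed Fisher exact probability for a 2x2 table
#'
#' Exact hypergeometric test with the minimum-likelihood two-tailed
#' convention: the p-value is the sum of the probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of the
#' observed table. This is the dominant convention in scientific software
#' (it is what `stats::fisher.test` computes for 2x2 tables).
#'
#' @param a,b,c,d non-negative integer cell counts of the table
#'   `rbind(c(a, b), c(c, d))`.
#' @return p-value in `[0, 1]`.
#' @examples
#' fisher_two_tailed(5, 0, 0, 5)  # 2/252
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  n <- sum(cells)
  if (n == 0) stop("all-zero table")
  r1 <- a + b
  c1 <- a + c
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Enrichment of an annotation set in a criticality category
#'
#' Measures how over- or under-represented an annotation (disease genes,
#' phosphorylated proteins, a neuron class, ...) is among the nodes of a
#' criticality category, relative to its frequency in the whole network.
#' With `f_d` the annotation fraction of the universe and `f_cat` its
#' fraction of the category, the enrichment score is `log2(f_cat / f_d)`;
#' significance comes from a two-tailed Fisher exact test on the 2x2 table
#' (in category vs not) x (annotated vs not). Annotation members absent
#' from the universe are dropped before counting. The 0.05 significance
#' convention is reported as a flag, never used as a filter.
#'
#' @param category_nodes character vector, the nodes of the category (must
#'   be a subset of `universe`).
#' @param annotation an [annotation_set()].
#' @param universe character vector of all network nodes.
#' @param exclude optional character vector removed from the universe (and
#'   from the category and annotation) before computing anything, e.g.
#'   receptors with zero in-degree.
#' @return An object of class `enrichment_result` with fields `label`,
#'   `n_universe`, `n_annotated`, `n_category`, `n_overlap`, `f_d`, `f_cat`,
#'   `score` (`-Inf` with `zero_overlap = TRUE` when the overlap is empty),
#'   `p_value`, `significant`.
#' @export
enrichment <- function(category_nodes, annotation, universe,
                       exclude = character(0)) {
  stopifnot(inherits(annotation, "annotation_set"))
  universe <- setdiff(unique(as.character(universe)), exclude)
  if (length(universe) == 0L) stop("empty universe")
  category_nodes <- setdiff(unique(as.character(category_nodes)), exclude)
  if (length(category_nodes) == 0L) stop("empty category")
  if (length(setdiff(category_nodes, universe))) {
    stop("category contains nodes outside the universe")
  }
  annotated <- intersect(annotation$members, universe)

  n_univ <- length(universe)
  n_ann <- length(annotated)
  n_cat <- length(category_nodes)
  n_ovl <- length(intersect(annotated, category_nodes))

  f_d <- n_ann / n_univ
  f_cat <- n_ovl / n_cat
  score <- if (n_ovl == 0L) -Inf
           else if (f_d == 0) NA_real_
           else log2(f_cat / f_d)

  p <- fisher_two_tailed(n_ovl, n_cat - n_ovl,
                         n_ann - n_ovl, n_univ - n_cat - n_ann + n_ovl)
  structure(
    list(label = annotation$label,
         n_universe = n_univ, n_annotated = n_ann,
         n_category = n_cat, n_overlap = n_ovl,
         f_d = f_d, f_cat = f_cat,
         score = score, zero_overlap = n_ovl == 0L,
         p_value = p, significant = p < 0.05),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> '", x$label, "': ", x$n_overlap, "/",
      x$n_category, " in category vs ", x$n_annotated, "/", x$n_universe,
      " in universe; score = ", format(round(x$score, 4)),
      ", p = ", format(signif(x$p_value, 4)),
      if (x$significant) " (p < 0.05)", "\n", sep = "")
  invisible(x)
}

#' Degree-ranked comparison sets for enrichment baselines
#'
#' Builds the two degree-based node sets used to benchmark the high
#' criticality set: *top degree* — the `|HCR|` highest-degree nodes, where
#' `|HCR|` is the number of high criticality nodes; *high degree* — the
#' `|HCR|` highest-degree nodes after first discarding the `|CMDS|`
#' highest-degree nodes (the analogue of excluding the critical nodes from
#' the high criticality set). Ties at any cut are broken by node-identifier
#' order, lexicographically smaller identifiers first.
#'
#' @param network a [directed_network()].
#' @param classification a `control_classification` from [classify_nodes()].
#' @param scores named criticality score vector.
#' @param k_kind which degree to rank by: `"total"`, `"in"` or `"out"`.
#' @param mode `"top"` or `"high"` (see above).
#' @return Character vector of node identifiers.
#' @export
degree_baseline_sets <- function(network, classification, scores,
                                 k_kind = c("total", "in", "out"),
                                 mode = c("top", "high")) {
  k_kind <- match.arg(k_kind)
  mode <- match.arg(mode)
  stopifnot(inherits(classification, "control_classification"))
  hcr <- names(scores)[scores > 0.5 & scores < 1]
  if (length(hcr) == 0L) stop("no high criticality nodes to match in size")
  deg <- node_degrees(network)
  val <- switch(k_kind,
                total = deg$in_degree + deg$out_degree,
                "in" = deg$in_degree,
                out = deg$out_degree)
  ord <- deg$node_id[order(-val, deg$node_id)]
  if (mode == "high") {
    ord <- ord[-seq_len(min(length(classification$cmds), length(ord)))]
  }
  ord[seq_len(min(length(hcr), length(ord)))]
}
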