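# Erdos-Renyi style random digraph with declared isolated nodes allowed.
random_digraph <- function(n, density, seed) {
  set.seed(seed)
  pairs <- expand.grid(src = seq_len(n), tgt = seq_len(n))
  pairs <- pairs[pairs$src != pairs$tgt, ]
  keep <- stats::runif(nrow(pairs)) < density
  ids <- paste0("v", seq_len(n))
  suppressWarnings(directed_network(
    cbind(ids[pairs$src[keep]], ids[pairs$tgt[keep]]), nodes = ids))
}

# canonical sortable key of a list of node sets
solution_key <- function(sets) {
  sort(vapply(sets, function(s) {
    m <- if (inherits(s, "node_subset")) s$members else s
    paste(sort(m), collapse = "|")
  }, character(1)))
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
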