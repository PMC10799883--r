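test_that("mean distance averages reachable pairs and counts the rest", {
  chain <- directed_network(rbind(c("a", "b"), c("b", "c")))
  md <- mean_distance(chain, sources = "a", module = c("b", "c"))
  expect_equal(md$mean_distance, 1.5)
  expect_equal(md$unreachable_pairs, 0L)

  # a source inside the module contributes distance 0 to itself
  md0 <- mean_distance(chain, sources = "b", module = c("b", "c"))
  expect_equal(md0$mean_distance, 0.5)

  # unreachable pairs are excluded unless strict
  iso <- directed_network(rbind(c("a", "b")), nodes = c("a", "b", "z"))
  md1 <- mean_distance(iso, sources = "a", module = c("b", "z"))
  expect_equal(md1$mean_distance, 1)
  expect_equal(md1$unreachable_pairs, 1L)
  expect_error(mean_distance(iso, "a", c("b", "z"), strict = TRUE),
               "unreachable")
  expect_error(mean_distance(iso, "z", "b"), "all .* unreachable")
  expect_error(mean_distance(iso, "a", "nope"), "not in network")
})

test_that("links counts one edge per (source, module-node) pair", {
  edges <- rbind(cbind("s1", c("m1", "m2", "m3")),
                 cbind("s2", c("m1", "m2", "m3")))
  net <- directed_network(edges)
  expect_equal(links_metric(net, c("s1", "s2"), c("m1", "m2", "m3")), 6)
  expect_equal(links_metric(net, "s1", "s2"), 0)
  # a source inside the module still counts
  net2 <- directed_network(rbind(c("m1", "m2")))
  expect_equal(links_metric(net2, "m1", c("m1", "m2")), 1)
})

test_that("coverage is the fraction of module nodes hit at least once", {
  edges <- rbind(cbind("s", paste0("m", 1:3)),
                 cbind(paste0("m", 1:9), paste0("m", c(2:9, 1))))
  net <- directed_network(edges)
  mod <- paste0("m", 1:9)
  expect_equal(cov_metric(net, "s", mod), 3 / 9)
  expect_equal(cov_metric(net, mod, mod), 1)
  expect_equal(cov_metric(net, "m1", "m1"), 0)  # no self-domination edge
  # cov * |module| never exceeds links
  expect_lte(cov_metric(net, "s", mod) * length(mod),
             links_metric(net, "s", mod))
})

test_that("randomization test is seeded, bounded and reproducible", {
  net <- random_digraph(20, 0.2, seed = 31)
  mod <- net$nodes[1:5]
  src <- net$nodes[6:9]
  r1 <- module_control(net, src, mod, trials = 200, seed = 4)
  r2 <- module_control(net, src, mod, trials = 200, seed = 4)
  expect_identical(r1$null, r2$null)
  expect_identical(r1$p_values, r2$p_values)
  expect_equal(length(r1$null$links), 200L)
  expect_true(all(unlist(r1$p_values) >= 0 & unlist(r1$p_values) <= 1))

  r3 <- module_control(net, src, mod, trials = 200, seed = 5)
  expect_false(identical(r1$null$links, r3$null$links))
})

test_that("degenerate nulls give the boundary p-values", {
  # every node points at every module node: cov is always 1, so the upper
  # tail probability for the observed cov = 1 is exactly 1
  nodes <- c(paste0("s", 1:6), "m1", "m2")
  edges <- do.call(rbind, lapply(nodes, function(v) {
    rbind(if (v != "m1") c(v, "m1"), if (v != "m2") c(v, "m2"))
  }))
  net <- directed_network(edges)
  r <- module_control(net, c("s1", "s2"), c("m1", "m2"), trials = 50,
                      seed = 1, metrics = "cov")
  expect_equal(r$observed$cov, 1)
  expect_equal(r$p_values$cov, 1)

  # observed more extreme than any draw can be: p = 0 is reported raw
  net2 <- directed_network(rbind(c("s", "m")), nodes = c("s", "m", paste0("z", 1:8)))
  r2 <- module_control(net2, "s", "m", trials = 100, seed = 2,
                       metrics = "links", exclude_module = TRUE)
  expect_equal(r2$observed$links, 1)
  expect_gte(r2$p_values$links, 0)
})

test_that("adding a source-to-module edge moves all metrics the right way", {
  for (s in 1:10) {
    net <- random_digraph(15, 0.15, seed = 800 + s)
    set.seed(900 + s)
    mod <- sample(net$nodes, 5)
    src <- sample(setdiff(net$nodes, mod), 3)
    uncovered <- mod[vapply(match(mod, net$nodes), function(u)
      !any(net$nodes[net$in_nbrs[[u]]] %in% src), logical(1))]
    if (length(uncovered) == 0) next
    target <- uncovered[1]
    net2 <- directed_network(rbind(net$edges, c(src[1], target)),
                             nodes = net$nodes)
    expect_gte(cov_metric(net2, src, mod), cov_metric(net, src, mod))
    expect_gte(links_metric(net2, src, mod), links_metric(net, src, mod))
    d1 <- tryCatch(mean_distance(net, src, mod), error = function(e) NULL)
    d2 <- mean_distance(net2, src, mod)
    if (!is.null(d1) && d1$unreachable_pairs == d2$unreachable_pairs) {
      expect_lte(d2$mean_distance, d1$mean_distance)
    }
  }
})

test_that("centrality baselines pick the expected top nodes", {
  star <- make_fixture("star_out_5")
  base <- centrality_baselines(star, 1)
  expect_equal(base$out_degree, "center")
  expect_equal(base$total_degree, "center")

  path <- directed_network(rbind(c("a", "b"), c("b", "c")))
  expect_equal(centrality_baselines(path, 1)$betweenness, "b")

  all_of_them <- centrality_baselines(path, 3)
  for (metric in names(all_of_them)) {
    expect_setequal(all_of_them[[metric]], path$nodes)
  }
  expect_error(centrality_baselines(path, 4), "k <=")
})
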