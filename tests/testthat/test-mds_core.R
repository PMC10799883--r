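# Frozen oracle values: brute force over all 16 subsets of the directed
# 4-cycle shows exactly two minimum dominating sets, {v1,v3} and {v2,v4}.

test_that("plain ILP solves recover known minimum dominating sets", {
  cyc <- make_fixture("directed_cycle_4")
  res <- solve_ilp(cyc, ilp_spec(cyc))
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, 2)
  expect_true(paste(sort(res$members), collapse = ",") %in%
                c("v1,v3", "v2,v4"))

  star <- make_fixture("star_out_5")
  res2 <- solve_ilp(star, ilp_spec(star))
  expect_equal(res2$members, "center")
})

test_that("hamming and cardinality constraints steer the solve", {
  cyc <- make_fixture("directed_cycle_4")
  spec <- ilp_spec(cyc,
                   hamming = list(list(members = c("v1", "v3"), k = 2)),
                   cardinality_equals = 2)
  res <- solve_ilp(cyc, spec)
  expect_equal(sort(res$members), c("v2", "v4"))

  # excluding both remaining solutions leaves nothing at cardinality 2
  spec2 <- ilp_spec(cyc,
                    hamming = list(list(members = c("v1", "v3"), k = 2),
                                   list(members = c("v2", "v4"), k = 2)),
                    cardinality_equals = 2)
  expect_equal(solve_ilp(cyc, spec2)$status, "infeasible")
})

test_that("forcing constraints validate and can make the program infeasible", {
  cyc <- make_fixture("directed_cycle_4")
  expect_error(ilp_spec(cyc, forced_in = "v1", forced_out = "v1"), "overlap")
  expect_error(ilp_spec(cyc, forced_in = "zz"), "undeclared")

  single <- directed_network(matrix(character(0), ncol = 2), nodes = "x")
  expect_equal(solve_ilp(single, ilp_spec(single, forced_out = "x"))$status,
               "infeasible")
})

test_that("minimum_dominating_set returns sets of the global minimum size", {
  expect_equal(length(minimum_dominating_set(make_fixture("fig1"))$members), 4L)
  expect_equal(length(minimum_dominating_set(make_fixture("directed_cycle_4"))$members), 2L)
  single <- directed_network(matrix(character(0), ncol = 2), nodes = "x")
  expect_equal(minimum_dominating_set(single)$members, "x")
})

test_that("every solver result passes the independent domination check", {
  for (s in 1:10) {
    net <- random_digraph(sample(6:12, 1), runif(1, 0.15, 0.5), seed = 300 + s)
    mds <- minimum_dominating_set(net)
    expect_true(verify_domination(net, mds$members))
  }
})

test_that("control categories match their definitions on fixtures", {
  star <- classify_nodes(make_fixture("star_out_5"))
  expect_equal(unname(star$categories["center"]), "critical")
  expect_true(all(star$categories[paste0("leaf", 1:5)] == "redundant"))

  cyc <- classify_nodes(make_fixture("directed_cycle_4"))
  expect_true(all(cyc$categories == "intermittent"))

  fig1 <- classify_nodes(make_fixture("fig1"))
  expect_equal(fig1$mds_size, 4L)
  expect_setequal(fig1$imds, c("v4", "v5", "v6", "v8", "v9", "v10"))
  expect_equal(fig1$cmds, "v1")
  expect_setequal(fig1$rmds, c("v2", "v3", "v7"))
})

test_that("classification agrees with the brute-force oracle on random digraphs", {
  for (s in 1:30) {
    set.seed(6000 + s)
    n <- sample(6:10, 1)
    net <- random_digraph(n, runif(1, 0.15, 0.5), seed = 6000 + s)
    cls <- classify_nodes(net)
    expect_identical(cls$categories[net$nodes], oracle_categories(net),
                     label = paste("graph seed", 6000 + s))
    # a node nobody points at can only dominate itself, hence is critical
    deg <- node_degrees(net)
    expect_true(all(cls$categories[deg$node_id[deg$in_degree == 0]] == "critical"))
  }
})

test_that("hamming distance is the symmetric difference size over one network", {
  cyc <- make_fixture("directed_cycle_4")
  a <- node_subset(c("v1", "v3"), cyc)
  b <- node_subset(c("v2", "v4"), cyc)
  expect_equal(hamming_distance(a, b), 4L)
  expect_equal(hamming_distance(a, a), 0L)
  expect_equal(hamming_distance(node_subset("v1", cyc),
                                node_subset(c("v1", "v2"), cyc)), 1L)
  expect_equal(sum(as_binary(a)), 2)

  other <- make_fixture("star_out_5")
  expect_error(hamming_distance(a, node_subset("center", other)),
               "different networks")
  expect_error(node_subset("nope", cyc), "not in network")
})
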