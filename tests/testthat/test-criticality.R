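test_that("initial Hamming bound follows the closed form", {
  fake <- function(m, cmds, imds) {
    structure(list(mds_size = m, cmds = cmds, imds = imds),
              class = "control_classification")
  }
  # |MDS|=4, |CMDS|=1, |IMDS|=6: h_max = min(3, 3) = 3, K = 2
  expect_equal(initial_k(fake(4L, "a", paste0("i", 1:6))), 2L)
  # 4-cycle: |MDS|=2, |CMDS|=0, |IMDS|=4: h_max = 2, K = 2
  expect_equal(initial_k(fake(2L, character(0), paste0("i", 1:4))), 2L)
  # unique MDS: K = -|MDS|, below the floor, loop never entered
  expect_equal(initial_k(fake(1L, "c", character(0))), -1L)
})

test_that("criticality scores are membership fractions", {
  nodes <- paste0("v", 1:4)
  sc <- criticality_scores(list(c("v1", "v3"), c("v2", "v4")), nodes)
  expect_equal(unname(sc), rep(0.5, 4))
  sc1 <- criticality_scores(list(c("v1", "v3")), nodes)
  expect_equal(unname(sc1), c(1, 0, 1, 0))
  expect_error(criticality_scores(list(), nodes), "empty")
})

test_that("dcr is the RMS change over intermittent nodes only", {
  a <- c(x = 0.5, y = 0.2, z = 1.0)
  expect_equal(dcr(a, a, c("x", "y")), 0)
  expect_equal(dcr(c(x = 0.5), c(x = 0.75), "x"), 0.25)
  prev <- setNames(rep(0.4, 4), paste0("i", 1:4))
  curr <- prev + 0.1
  expect_equal(dcr(prev, curr, names(prev)), 0.1)
  expect_error(dcr(a, a, character(0)), "undefined")
})

test_that("exhaustive enumeration reproduces the worked example", {
  res <- compute_criticality(make_fixture("fig1"), theta = 0)
  expect_equal(length(res$solutions), 4L)
  expect_equal(res$classification$mds_size, 4L)
  expect_equal(unname(res$scores[c("v4", "v5", "v6")]), rep(0.75, 3))
  expect_equal(unname(res$scores[c("v8", "v9", "v10")]), rep(0.25, 3))
  expect_equal(unname(res$scores["v1"]), 1)
  expect_equal(res$converged_by, "k_floor")
})

test_that("exhaustive enumeration matches closed forms on small fixtures", {
  res <- compute_criticality(make_fixture("directed_cycle_4"), theta = 0)
  expect_equal(length(res$solutions), 2L)
  expect_equal(unname(res$scores), rep(0.5, 4))

  res2 <- compute_criticality(make_fixture("star_out_5"), theta = 0.05)
  expect_equal(length(res2$solutions), 1L)
  expect_equal(unname(res2$scores["center"]), 1)
  expect_true(all(res2$scores[paste0("leaf", 1:5)] == 0))
})

test_that("no solution is enumerated twice and all have size |MDS|", {
  for (s in 1:15) {
    set.seed(7000 + s)
    net <- random_digraph(sample(6:12, 1), runif(1, 0.15, 0.5), seed = 7000 + s)
    res <- compute_criticality(net, theta = 0)
    m <- res$classification$mds_size
    expect_true(all(lengths(res$solutions) == m))
    expect_false(any(duplicated(solution_key(res$solutions))))
    # cumulative count per round is non-decreasing by construction
    expect_true(all(res$rounds$solutions_found >= 0))
    expect_equal(sum(res$rounds$solutions_found) + 1L, length(res$solutions))
  }
})

test_that("score mass is conserved and category scores pinned at any theta", {
  for (s in 1:10) {
    set.seed(7100 + s)
    net <- random_digraph(sample(6:12, 1), runif(1, 0.15, 0.5), seed = 7100 + s)
    for (theta in c(0, 0.01, 0.1)) {
      res <- compute_criticality(net, theta = theta)
      expect_equal(sum(res$scores), res$classification$mds_size)
      expect_true(all(res$scores[res$classification$cmds] == 1))
      expect_true(all(res$scores[res$classification$rmds] == 0))
      expect_true(all(res$scores >= 0 & res$scores <= 1))
    }
  }
})

test_that("score-based categories use the strict-above-threshold rule", {
  sc <- c(a = 0.75, b = 0.25, c = 1.0, d = 0.0, e = 0.5)
  cat <- classify_by_score(sc)
  expect_equal(unname(cat), c("high", "low", "critical", "redundant", "low"))
  expect_true(all(classify_by_score(c(x = 1, y = 1)) == "critical"))
  expect_error(classify_by_score(sc, threshold = 0), "threshold")
  expect_error(classify_by_score(sc, threshold = 1.2), "threshold")
  expect_error(classify_by_score(c(a = 1.3)), "0, 1")
})

test_that("the run trace records the descending K ladder", {
  res <- compute_criticality(make_fixture("fig1"), theta = 0)
  expect_equal(res$rounds$k, c(2L, 0L, -2L))
  expect_true(is.na(res$rounds$dcr[1]))
  expect_true(all(diff(res$rounds$k) == -2L))
  # floor is 2 - |MDS|
  expect_equal(min(res$rounds$k), 2L - res$classification$mds_size)
})
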