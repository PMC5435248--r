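test_that("pearson matches the hand-computed closed form and handles edge cases", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  # hand computation: r = 15.25 / sqrt(8.75 * 26.75) = 0.9967906
  expect_equal(pearson(c(1, 2, 3, 5), c(2, 4, 6, 9)), 0.9967906,
               tolerance = 1e-7)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:3, 1:4), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("edge confusion on a small worked example", {
  truth <- signaling_network(data.frame(
    source = c("A", "B"), interaction = "activates", target = c("B", "C")
  ), quiet = TRUE)
  m <- edge_confusion(truth, data.frame(source = c("A", "A"),
                                        target = c("B", "C")))
  expect_identical(m$tp, 1L)
  expect_identical(m$fp, 1L)
  expect_identical(m$fn, 1L)
  expect_identical(m$precision, 0.5)
  expect_identical(m$recall, 0.5)
  expect_identical(m$sensitivity, m$recall)
  expect_equal(m$f1, 0.5)
})

test_that("perfect and empty predictions give the boundary metrics", {
  truth <- signaling_network(data.frame(
    source = c("A", "B"), interaction = c("activates", "inhibits"),
    target = c("B", "C")
  ), quiet = TRUE)
  perfect <- edge_confusion(truth, truth)
  expect_identical(perfect$precision, 1)
  expect_identical(perfect$recall, 1)

  expect_warning(
    none <- edge_confusion(truth, data.frame(source = character(),
                                             target = character())),
    "precision undefined"
  )
  expect_identical(none$recall, 0)
  expect_true(is.nan(none$precision))
})

test_that("duplicates and prediction order do not change the metrics", {
  truth <- signaling_network(data.frame(
    source = c("A", "B", "C"), interaction = "activates",
    target = c("B", "C", "D")
  ), quiet = TRUE)
  pred <- data.frame(source = c("A", "B", "A", "D"),
                     target = c("B", "C", "B", "A"))
  a <- suppressWarnings(edge_confusion(truth, pred))
  b <- suppressWarnings(edge_confusion(truth, pred[sample(nrow(pred)), ]))
  expect_identical(a[c("tp", "fp", "fn")], b[c("tp", "fp", "fn")])
  expect_identical(a$tp, 2L)  # duplicate A->B collapses
  expect_identical(a$fp, 1L)
})

test_that("binds edges match either direction; strict mode needs the right sign", {
  truth <- signaling_network(data.frame(
    source = c("A", "B"), interaction = c("binds", "inhibits"),
    target = c("B", "C")
  ), quiet = TRUE)
  m <- edge_confusion(truth, data.frame(source = c("B", "C"),
                                        target = c("A", "B")))
  expect_identical(m$tp, 1L)  # B->A hits the undirected binds edge
  expect_identical(m$fp, 1L)  # C->B does not hit directed B-inhibits-C

  undir <- edge_confusion(truth, data.frame(source = c("B", "C"),
                                            target = c("A", "B")),
                          mode = "undirected")
  expect_identical(undir$tp, 2L)

  strict_wrong <- edge_confusion(
    truth, data.frame(source = "B", target = "C",
                      interaction = "activates"), strict = TRUE
  )
  expect_identical(strict_wrong$tp, 0L)
  strict_right <- edge_confusion(
    truth, data.frame(source = "B", target = "C",
                      interaction = "weakly inhibits"), strict = TRUE
  )
  expect_identical(strict_right$tp, 1L)
})

test_that("unknown predicted nodes warn and count as false positives", {
  truth <- signaling_network(data.frame(
    source = "A", interaction = "activates", target = "B"
  ), quiet = TRUE)
  expect_warning(
    m <- edge_confusion(truth, data.frame(source = "A", target = "Z")),
    "not in the truth"
  )
  expect_identical(m$fp, 1L)
})

test_that("edge confusion agrees with exhaustive set arithmetic on random pairs", {
  set.seed(500)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    nodes <- LETTERS[seq_len(n)]
    truth_df <- random_edge_table(n, sample(1:15, 1),
                                  terms = c("activates", "inhibits",
                                            "weakly activates"))
    truth <- signaling_network(truth_df, nodes = nodes, quiet = TRUE)
    k <- sample(1:15, 1)
    pred <- data.frame(source = sample(nodes, k, replace = TRUE),
                       target = sample(nodes, k, replace = TRUE))
    got <- edge_confusion(truth, pred)
    want <- brute_force_confusion(
      paste(truth_df$source, truth_df$target),
      paste(pred$source, pred$target)
    )
    expect_identical(got$tp, as.integer(want$tp))
    expect_identical(got$fp, as.integer(want$fp))
    expect_identical(got$fn, as.integer(want$fn))
    expect_true(is.nan(got$precision) ||
                  (got$precision >= 0 && got$precision <= 1))
    expect_true(got$recall >= 0 && got$recall <= 1)
  }
})

test_that("scoring a trajectory against its own mean gives correlation 1", {
  net <- strength_demo_network()
  ts <- simulate(net, config = sim_config(n_replicates = 5, n_timepoints = 10,
                                          noise_pct = 5, seed = 14))
  m <- replicate_means(ts)
  ref <- data.frame(
    time = rep(as.numeric(rownames(m)), times = 3),
    node = rep(c("E", "F", "G"), each = nrow(m)),
    value = c(m[, "E"], m[, "F"], m[, "G"])
  )
  res <- score_against_reference(ts, ref)
  expect_equal(unname(res$per_node), rep(1, 3), tolerance = 1e-12)
  expect_equal(res$overall, 1, tolerance = 1e-12)

  # Pearson is location-invariant
  ref$value <- ref$value + 10
  res2 <- score_against_reference(ts, ref)
  expect_equal(unname(res2$per_node), rep(1, 3), tolerance = 1e-12)
})

test_that("time-scale alignment matches the right simulated steps", {
  net <- strength_demo_network()
  ts <- simulate(net, config = sim_config(n_replicates = 4, n_timepoints = 10,
                                          seed = 5))
  m <- replicate_means(ts)
  # reference sampled at 0, 1, 2, 3 minutes with 0.5 min per step
  steps <- c(0, 2, 4, 6)
  ref <- data.frame(time = steps * 0.5, node = "G",
                    value = m[as.character(steps), "G"])
  res <- score_against_reference(ts, ref, time_scale = 0.5)
  expect_equal(unname(res$per_node[["G"]]), 1, tolerance = 1e-12)
  expect_identical(unname(res$n_pairs[["G"]]), 4)

  expect_error(score_against_reference(ts, data.frame(time = 100, node = "G",
                                                      value = 1)),
               "no overlapping")
  expect_error(score_against_reference(ts, data.frame(time = 0, node = "ZZ",
                                                      value = 1)),
               "absent")
})

test_that("a two-node toy reference matches a spreadsheet-style computation", {
  net <- signaling_network(data.frame(
    source = "A", interaction = "activates", target = "B"
  ), quiet = TRUE)
  cfg <- sim_config(n_replicates = 1, n_timepoints = 4,
                    baseline = c(A = 50, B = 50), seed = 1)
  ts <- simulate(net, config = cfg)
  m <- replicate_means(ts)
  ref_b <- c(50, 54, 58, 61, 64)  # roughly linear rise
  res <- score_against_reference(ts, data.frame(time = 0:4, node = "B",
                                                value = ref_b))
  # independent closed-form check with raw vectors
  expect_equal(res$per_node[["B"]], cor(m[, "B"], ref_b), tolerance = 1e-12)
})
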