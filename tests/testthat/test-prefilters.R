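# Gini-importance and chi-square filter tests: hand-computed importances on
# fixed trees, property tests on random trees, and an independent
# contingency-table oracle for the chi-square statistic.

test_that("node_importance matches hand arithmetic", {
  stump <- tree_node(10, 0.5, split_feature = 1,
                     left = tree_node(6, 0.2), right = tree_node(4, 0.3))
  expect_equal(node_importance(stump), 10 * 0.5 - 6 * 0.2 - 4 * 0.3)  # 2.6
  expect_equal(node_importance(stump), 2.6)

  pure <- tree_node(8, 0.4, split_feature = 2,
                    left = tree_node(5, 0), right = tree_node(3, 0))
  expect_equal(node_importance(pure), 8 * 0.4)

  flat <- tree_node(10, 0.5, split_feature = 1,
                    left = tree_node(6, 0.5), right = tree_node(4, 0.5))
  expect_equal(node_importance(flat), 0)

  expect_error(node_importance(tree_node(4, 0.1)), "internal")
})

test_that("tree_feature_importance matches the hand-enumerated two-split tree", {
  tr <- two_split_tree()
  # root (feature 1): 10*0.5 - 6*0.2 - 4*0.3 = 2.6
  # left (feature 2): 6*0.2 - 4*0 - 2*0.5 = 0.2 ; total = 2.8
  imp <- tree_feature_importance(tr)
  expect_equal(imp$raw, c(2.6 / 2.8, 0.2 / 2.8, 0))
  expect_equal(imp$normalized, c(13 / 14, 1 / 14, 0))
  expect_equal(sum(imp$normalized), 1)

  single <- decision_tree(
    tree_node(5, 0.5, split_feature = 1,
              left = tree_node(3, 0.2), right = tree_node(2, 0.1)), 4L)
  expect_equal(tree_feature_importance(single)$normalized, c(1, 0, 0, 0))

  expect_error(tree_feature_importance(decision_tree(tree_node(5, 0.2), 2L)),
               "no internal nodes")
})

test_that("normalized importances sum to 1 on random trees", {
  set.seed(31)
  for (i in 1:50) {
    tr <- random_tree(n_features = sample(2:6, 1))
    expect_equal(sum(tree_feature_importance(tr)$normalized), 1,
                 tolerance = 1e-12)
  }
})

test_that("forest_feature_importance averages normalized vectors", {
  tr <- two_split_tree()
  single <- forest_feature_importance(list(tr))
  expect_equal(single$forest_averaged, tree_feature_importance(tr)$normalized)
  expect_equal(forest_feature_importance(list(tr, tr, tr))$forest_averaged,
               tree_feature_importance(tr)$normalized)

  # brute-force equivalence on a random forest of hand-representable trees
  set.seed(17)
  trees <- lapply(1:20, function(i) random_tree(4L))
  got <- forest_feature_importance(trees)$forest_averaged
  brute <- Reduce(`+`, lapply(trees, function(t) tree_feature_importance(t)$normalized)) / 20
  expect_equal(got, brute, tolerance = 1e-12)

  t_bad <- decision_tree(two_split_tree()$root, 5L)
  expect_error(forest_feature_importance(list(tr, t_bad)), "same n_features")
})

test_that("chi_square_score matches the formula and the stats oracle", {
  expect_equal(chi_square_score(c(10, 20), c(15, 15))$statistic, 10 / 3)
  expect_equal(chi_square_score(c(5, 5), c(5, 5))$statistic, 0)
  expect_error(chi_square_score(c(1, 2), c(1, 0)), "> 0")
  expect_error(chi_square_score(c(1, 2), c(1, 2, 3)), "equal length")

  # independent oracle: Pearson statistic of chisq.test (no correction) on
  # random 2x2 tables with margin-derived expectations
  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ours <- chi_square_score(as.numeric(tab), as.numeric(expected))$statistic
    oracle <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
    expect_equal(ours, unname(oracle), tolerance = 1e-12)
  }
})

test_that("chi_square_score is permutation invariant and scales linearly", {
  set.seed(5)
  for (i in 1:20) {
    pair <- random_table_pair(6)
    s <- chi_square_score(pair$observed, pair$expected)$statistic
    perm <- sample(6)
    expect_equal(chi_square_score(pair$observed[perm], pair$expected[perm])$statistic,
                 s, tolerance = 1e-12)
    c_scale <- runif(1, 0.5, 4)
    expect_equal(
      chi_square_score(c_scale * pair$observed, c_scale * pair$expected)$statistic,
      c_scale * s, tolerance = 1e-10
    )
  }
})

test_that("chi_square_feature_scores separates informative from independent", {
  set.seed(8)
  n <- 400
  y <- rep(0:1, each = n / 2)
  x <- cbind(
    label_copy = y + rnorm(n, sd = 0.01),
    independent = rnorm(n),
    constant = rep(1, n)
  )
  scores <- suppressWarnings(chi_square_feature_scores(x, y))
  expect_gt(scores[1], scores[2])
  expect_equal(scores[3], 0)
  expect_warning(chi_square_feature_scores(x, y), "constant")
  expect_equal(which.max(scores), 1L)
})

test_that("grown trees and forests rank planted features highly", {
  d <- generate_features(synthetic_spec(
    n_samples = 300, n_informative = 3, n_redundant = 0, n_noise = 12,
    effect_size = 1.5, seed = 21
  ))
  g <- gini_feature_scores(d$x, d$y, n_trees = 15, seed = 3)
  expect_equal(sum(g), 1, tolerance = 1e-9)
  # every informative feature ranked above the median
  ranks <- rank(-g, ties.method = "first")
  expect_true(all(ranks[d$informative] <= ncol(d$x) / 2))
})

test_that("prefilter keeps top-ranked indices with deterministic ties", {
  d <- oracle_dataset()
  idx_all <- prefilter(d$x, d$y, method = "chi2", keep = ncol(d$x))
  expect_identical(idx_all, seq_len(ncol(d$x)))

  idx <- prefilter(d$x, d$y, method = "chi2", keep = 3)
  expect_length(idx, 3L)
  expect_true(all(diff(idx) > 0))
  # the three planted informative features carry the dependency signal
  expect_gte(length(intersect(idx, d$informative)), 2L)

  idx_g <- prefilter(d$x, d$y, method = "gini", keep = 3, n_trees = 15, seed = 2)
  expect_gte(length(intersect(idx_g, d$informative)), 2L)

  expect_error(prefilter(d$x, d$y, method = "chi2", keep = 0), "keep")
  expect_error(prefilter(d$x, d$y, method = "chi2", keep = 99), "keep")
})
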