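# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# A hand-built two-split tree whose importances are computed by hand in the
# tests: root splits on feature 1, its left child on feature 2.
two_split_tree <- function(n_features = 3L) {
  left <- tree_node(
    6, 0.2, split_feature = 2,
    left = tree_node(4, 0), right = tree_node(2, 0.5)
  )
  root <- tree_node(
    10, 0.5, split_feature = 1,
    left = left, right = tree_node(4, 0.3)
  )
  decision_tree(root, n_features)
}

# Random tree with valid structure: child weights sum to the parent's,
# impurities in [0, 0.5], split features drawn at random.
random_tree <- function(n_features, max_depth = 4L) {
  build <- function(w, depth) {
    imp <- runif(1, 0, 0.5)
    if (depth >= max_depth || w < 2 || runif(1) < 0.3) {
      return(tree_node(w, imp))
    }
    wl <- max(1, round(runif(1, 0.2, 0.8) * w))
    wr <- w - wl
    if (wr < 1) return(tree_node(w, imp))
    tree_node(w, imp, split_feature = sample.int(n_features, 1L),
              left = build(wl, depth + 1L), right = build(wr, depth + 1L))
  }
  root <- build(sample(20:60, 1L), 0L)
  # ensure at least one split
  if (is.null(root$split_feature)) {
    root <- tree_node(
      root$weighted_samples + 2, root$impurity,
      split_feature = sample.int(n_features, 1L),
      left = tree_node(root$weighted_samples, root$impurity),
      right = tree_node(2, 0.1)
    )
  }
  decision_tree(root, n_features)
}

# Random contingency-style observed/expected pair with all-positive expected.
random_table_pair <- function(n_cells = 4L) {
  observed <- rpois(n_cells, lambda = 10) + 1
  expected <- runif(n_cells, 2, 20)
  list(observed = observed, expected = expected)
}

# Small planted dataset for wrapper tests: 3 informative, 5 noise, n = 120.
oracle_dataset <- function(seed = 11L) {
  generate_features(synthetic_spec(
    n_samples = 120L, n_informative = 3L, n_redundant = 0L, n_noise = 5L,
    effect_size = 1.5, seed = seed
  ))
}

constant_objective <- function(value = 7) function(x) value
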