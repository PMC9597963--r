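test_that("importance fractions are normalized, ordered and tie-broken", {
  fx <- small_fixture()
  imp <- feature_importance(fx$fit)
  expect_equal(sum(imp$gain_fraction), 1, tolerance = 1e-9)
  expect_true(all(imp$gain_fraction >= 0))
  expect_true(all(diff(imp$gain) <= 1e-9))
  expect_equal(imp$rank, seq_len(nrow(imp)))
  ties <- imp[duplicated(imp$gain) | duplicated(imp$gain, fromLast = TRUE), ]
  if (nrow(ties) > 1) {
    by_gain <- split(ties$feature, ties$gain)
    for (grp in by_gain) expect_equal(grp, sort(grp))
  }
})

test_that("a single-split model credits its one feature with everything", {
  fx <- small_fixture()
  sub <- 1:200
  m <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub],
    hyper_params(max_depth = 1, learning_rate = 1),
    best_iterations = 1)
  imp <- feature_importance(m)
  expect_equal(nrow(imp), 1)
  expect_equal(imp$gain_fraction, 1)
})

test_that("a zero-split model warns and yields an empty table", {
  fx <- small_fixture()
  m0 <- train_final(fx$feats[1:60, ], fx$sim$efficiency[1:60],
    hyper_params(), best_iterations = c(0))
  expect_warning(imp <- feature_importance(m0),
    class = "guideboost_empty_model_warning")
  expect_equal(nrow(imp), 0)
})

test_that("recorded gains equal the brute-force SSE reduction per split", {
  # one shallow tree: recompute every split's gain from the raw data
  fx <- small_fixture()
  sub <- 1:300
  feats <- fx$feats[sub, ]
  y <- fx$sim$efficiency[sub]
  m <- train_final(feats, y, hyper_params(max_depth = 2, learning_rate = 1),
    best_iterations = 1)
  tree <- export_tree(m, 0, features = feats, y = y)
  splits <- tree[!tree$leaf, ]
  expect_gte(nrow(splits), 2)
  r <- y - mean(y)
  enc <- guideboost:::encode_features(feats, m$schema)
  X <- enc$X
  attr(X, "schema_levels") <- stats::setNames(m$schema$levels,
    m$schema$feature)
  membership <- guideboost:::route_rows(tree, X)
  sse <- function(v) sum((v - mean(v))^2)
  for (i in seq_len(nrow(splits))) {
    nd <- splits[i, ]
    parent <- r[membership[[as.character(nd$nodeid)]]]
    yes <- r[membership[[as.character(nd$yes)]]]
    no <- r[membership[[as.character(nd$no)]]]
    brute <- sse(parent) - sse(yes) - sse(no)
    expect_equal(nd$gain, brute, tolerance = 1e-3)
  }
  imp <- feature_importance(m)
  expect_equal(sum(imp$gain), sum(splits$gain), tolerance = 1e-9)
})

test_that("contribution decomposition is exactly additive", {
  fx <- small_fixture()
  n <- 1000
  sim <- quiet(simulate_dataset(generator_config(n_guides = n, seed = 31)))
  feats <- stub_featurize(sim$sequence30)
  cb <- predict_contributions(fx$fit, feats)
  per_row <- dplyr::summarise(cb,
    err = abs(base_value[1] + sum(contribution) - prediction[1]),
    .by = ".row")
  expect_equal(nrow(per_row), n)
  expect_lt(max(per_row$err), 1e-6)
  # and the breakdown's prediction is the model's prediction
  expect_equal(unique(cb$prediction[cb$.row == 1]),
    predict(fx$fit, feats[1, ]))
})

test_that("zero-tree models contribute nothing", {
  fx <- small_fixture()
  m0 <- train_final(fx$feats[1:60, ], fx$sim$efficiency[1:60],
    hyper_params(), best_iterations = c(0))
  cb <- predict_contributions(m0, fx$feats[1:5, ])
  expect_true(all(cb$contribution == 0))
  expect_equal(unique(cb$prediction), m0$base_value)
})

test_that("the same feature can contribute differently for different guides", {
  fx <- small_fixture()
  cb <- predict_contributions(fx$fit, fx$feats[1:20, ])
  spread <- dplyr::summarise(cb,
    distinct = dplyr::n_distinct(round(contribution, 9)),
    .by = "feature")
  expect_gt(max(spread$distinct), 1)
  top <- top_contributions(cb, row = 1, n = 10)
  expect_equal(nrow(top), 10)
  expect_true(all(diff(abs(top$contribution)) <= 1e-12))
})

test_that("exported trees carry branch-mean internal values", {
  fx <- small_fixture()
  y <- fx$sim$efficiency
  t0 <- export_tree(fx$fit, 0, features = fx$feats, y = y)
  expect_equal(t0$internal_value[t0$nodeid == 0], mean(y), tolerance = 1e-6)
  t1 <- export_tree(fx$fit, 1, features = fx$feats, y = y)
  expect_lt(abs(t1$internal_value[t1$nodeid == 0]), 1e-6)
  # leaf-aggregation fallback agrees closely without the data
  t1b <- export_tree(fx$fit, 1)
  expect_lt(abs(t1b$internal_value[t1b$nodeid == 0]), 1e-4)
  expect_error(export_tree(fx$fit, fx$fit$n_trees),
    class = "guideboost_param_error")
  expect_error(export_tree(fx$fit, -1), class = "guideboost_param_error")
})

test_that("depth truncation bounds the exported internal nodes", {
  fx <- small_fixture()
  tr <- export_tree(fx$fit, 0, max_depth = 3)
  expect_true(all(tr$depth <= 3))
  expect_lte(sum(!tr$leaf & tr$depth < 3), 7) # 2^3 - 1
})

test_that("categorical splits report category subsets, not thresholds", {
  fx <- small_fixture()
  nodes <- dplyr::bind_rows(guideboost:::parse_trees(fx$fit))
  cat_splits <- nodes[!nodes$leaf & nodes$split_type == "categorical", ]
  expect_gt(nrow(cat_splits), 0)
  vocab2 <- guideboost:::kmer_vocab(2)
  for (i in seq_len(min(20, nrow(cat_splits)))) {
    cats <- cat_splits$categories[[i]]
    expect_gt(length(cats), 0)
    expect_true(all(cats %in% c("A", "C", "G", "T", vocab2)))
    expect_true(is.na(cat_splits$threshold[i]))
  }
})

test_that("tree exports render to Graphviz DOT", {
  fx <- small_fixture()
  tr <- export_tree(fx$fit, 0, features = fx$feats, y = fx$sim$efficiency,
    max_depth = 3)
  path <- withr::local_tempfile(fileext = ".dot")
  write_tree_dot(tr, path)
  dot <- readLines(path)
  expect_match(dot[1], "digraph")
  expect_true(any(grepl("internal_value", dot)))
  expect_true(any(grepl("shape=oval", dot)) || any(grepl("shape=box", dot)))
})

test_that("importance and contribution plots build", {
  fx <- small_fixture()
  p1 <- plot_importance(fx$fit, top_n = 10)
  expect_s3_class(p1, "ggplot")
  cb <- predict_contributions(fx$fit, fx$feats[1:2, ])
  p2 <- plot_contributions(cb, row = 1, top_n = 5)
  expect_s3_class(p2, "ggplot")
  expect_s3_class(ggplot2::autoplot(fx$fit), "ggplot")
  td <- tidy(fx$fit)
  expect_equal(sum(td$gain_fraction), 1, tolerance = 1e-9)
})
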