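test_that("fold assignment is deterministic, balanced and reusable", {
  f <- make_folds(10, 10, seed = 1)
  expect_setequal(f, 1:10) # singleton folds
  f1 <- make_folds(103, 10, seed = 42)
  f2 <- make_folds(103, 10, seed = 42)
  expect_identical(f1, f2)
  sizes <- table(f1)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(make_folds(5, 10, seed = 1), class = "guideboost_param_error")
})

test_that("constant response gives zero validation MSE", {
  fx <- small_fixture()
  y_const <- rep(42, nrow(fx$feats))
  res <- cv_evaluate(fx$feats[1:100, ], y_const[1:100],
    params = hyper_params(), cv = cv_config(k_folds = 4, max_trees = 20))
  expect_equal(res$mean_mse, 0, tolerance = 1e-10)
  expect_true(is.na(res$mean_spearman))
})

test_that("CV detects planted signal and not permuted labels", {
  sim <- quiet(simulate_dataset(generator_config(n_guides = 2000, seed = 23)))
  feats <- stub_featurize(sim$sequence30)
  res <- cv_evaluate(feats, sim$efficiency,
    params = hyper_params(learning_rate = 0.1),
    cv = cv_config(k_folds = 5, max_trees = 400), seed = 1)
  # reference-run pin: 0.508 under these exact seeds and sizes
  expect_gte(res$mean_spearman, 0.45)
  expect_length(res$best_iterations, 5)

  y_perm <- withr::with_seed(9, sample(sim$efficiency))
  null_res <- cv_evaluate(feats, y_perm,
    params = hyper_params(learning_rate = 0.1),
    cv = cv_config(k_folds = 5, max_trees = 50), seed = 1)
  expect_lt(abs(null_res$mean_spearman), 0.1)
})

test_that("Bayesian optimization finds a 1-D quadratic optimum", {
  obj <- function(p) -(p$x - 1.7)^2
  res <- bayesian_optimize(obj, bounds = list(x = list(lower = 0, upper = 5)),
    n_init = 10, n_iter = 25, seed = 4)
  expect_lt(abs(res$best_params$x - 1.7), 0.05 * 5)
  # same seed => identical trace
  res2 <- bayesian_optimize(obj, bounds = list(x = list(lower = 0, upper = 5)),
    n_init = 10, n_iter = 25, seed = 4)
  expect_identical(res$trace, res2$trace)
})

test_that("Bayesian optimization budget and failure handling", {
  obj <- function(p) -(p$x - 2)^2
  res0 <- bayesian_optimize(obj, bounds = list(x = list(lower = 0, upper = 5)),
    n_init = 10, n_iter = 0, seed = 1)
  expect_equal(nrow(res0$trace), 10)
  expect_equal(res0$best_score, max(res0$trace$score))

  flaky <- function(p) {
    if (p$x > 2.5) stop("unstable region")
    -(p$x - 2)^2
  }
  resf <- bayesian_optimize(flaky,
    bounds = list(x = list(lower = 0, upper = 5)),
    n_init = 10, n_iter = 10, seed = 2)
  expect_true(any(resf$trace$failed))
  expect_true(any(!resf$trace$failed))
  expect_lte(resf$best_params$x, 2.5)

  expect_error(
    bayesian_optimize(function(p) stop("no"),
      bounds = list(x = list(lower = 0, upper = 1)),
      n_init = 3, n_iter = 2, seed = 1),
    class = "guideboost_optimization_error"
  )
})

test_that("integer and log dimensions are decoded correctly", {
  seen <- list()
  obj <- function(p) {
    seen[[length(seen) + 1]] <<- p
    -(log(p$rate) + 2)^2 - (p$depth - 6)^2
  }
  res <- bayesian_optimize(obj, bounds = list(
    rate = list(lower = 0.005, upper = 0.3, log = TRUE),
    depth = list(lower = 3, upper = 12, integer = TRUE)
  ), n_init = 8, n_iter = 12, seed = 3)
  depths <- vapply(seen, `[[`, numeric(1), "depth")
  rates <- vapply(seen, `[[`, numeric(1), "rate")
  expect_true(all(depths == round(depths)))
  expect_true(all(depths >= 3 & depths <= 12))
  expect_true(all(rates >= 0.005 & rates <= 0.3))
})

test_that("final training uses the round-half-even mean tree count", {
  fx <- small_fixture()
  sub <- 1:150
  m1 <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub],
    hyper_params(), best_iterations = rep(10, 10))
  expect_equal(m1$n_trees, 10L)
  m2 <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub],
    hyper_params(), best_iterations = c(9, 11, 11, 9, 10, 11))
  expect_equal(m2$n_trees, round(mean(c(9, 11, 11, 9, 10, 11))))
  m3 <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub],
    hyper_params(), best_iterations = c(10, 11)) # mean 10.5, half-even -> 10
  expect_equal(m3$n_trees, 10L)
  expect_error(
    train_final(fx$feats[sub, ], fx$sim$efficiency[sub], hyper_params(),
      best_iterations = numeric(0)),
    class = "guideboost_param_error"
  )
})

test_that("base value is the training grand mean and zero-tree models predict it", {
  fx <- small_fixture()
  expect_equal(fx$fit$base_value, mean(fx$sim$efficiency), tolerance = 1e-6)
  sub <- 1:80
  m0 <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub],
    hyper_params(), best_iterations = c(0, 0, 0))
  expect_equal(m0$n_trees, 0L)
  p <- predict(m0, fx$feats[sub, ])
  expect_equal(p, rep(mean(fx$sim$efficiency[sub]), length(sub)))
})

test_that("training is deterministic given fixed seeds", {
  fx <- small_fixture()
  sub <- 1:200
  p <- hyper_params(learning_rate = 0.15, bagging_fraction = 0.8,
    feature_fraction = 0.8)
  m1 <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub], p,
    best_iterations = 40, seed = 7)
  m2 <- train_final(fx$feats[sub, ], fx$sim$efficiency[sub], p,
    best_iterations = 40, seed = 7)
  expect_identical(
    xgboost::xgb.save.raw(m1$booster),
    xgboost::xgb.save.raw(m2$booster)
  )
  expect_equal(predict(m1, fx$feats[sub, ]), predict(m2, fx$feats[sub, ]))
})

test_that("schema violations and unseen categories are handled", {
  fx <- small_fixture()
  expect_error(predict(fx$fit, fx$feats[, -2]),
    class = "guideboost_schema_error")
  odd <- fx$feats[1:3, ]
  odd$di19 <- factor(c("ZZ", "AA", "AA"), levels = c("ZZ", "AA"))
  expect_warning(p <- predict(fx$fit, odd),
    class = "guideboost_unseen_level_warning")
  expect_true(all(is.finite(p)))
})

test_that("planted poly-T penalty shows up as lower predictions", {
  fx <- small_fixture()
  pred <- predict(fx$fit, fx$feats)
  runs <- fx$feats$max_polyT
  expect_lt(mean(pred[runs >= 4]), mean(pred[runs <= 2]))
})

test_that("models round-trip through disk persistence", {
  fx <- small_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_guideboost(fx$fit, path)
  expect_true(file.exists(paste0(path, ".sidecar.json")))
  back <- read_guideboost(path)
  expect_equal(back$base_value, fx$fit$base_value)
  expect_equal(back$n_trees, fx$fit$n_trees)
  expect_equal(predict(back, fx$feats[1:50, ]),
    predict(fx$fit, fx$feats[1:50, ]))
  gl <- glance(back)
  expect_equal(gl$n_features, 149L)
})

test_that("tuning returns the best hyperparameters with a full trace", {
  fx <- small_fixture()
  sub <- 1:300
  tuned <- tune_guideboost(fx$feats[sub, ], fx$sim$efficiency[sub],
    bounds = list(
      learning_rate = list(lower = 0.05, upper = 0.3, log = TRUE),
      max_depth = list(lower = 3, upper = 8, integer = TRUE)
    ),
    cv = cv_config(k_folds = 3, max_trees = 60),
    n_init = 3, n_iter = 2, seed = 5)
  expect_s3_class(tuned$best_params, "guideboost_params")
  expect_equal(nrow(tuned$trace), 5)
  expect_equal(-max(tuned$trace$score), tuned$best_cv$mean_mse,
    tolerance = 1e-9)
})
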