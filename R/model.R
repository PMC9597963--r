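#' Hyperparameters for the boosted-tree learner
#'
#' The six tuned quantities: shrinkage (`learning_rate`), tree shape
#' (`max_depth`, `num_leaves`), histogram resolution (`max_bin`), and column
#' / row subsampling fractions. Defaults are sensible mid-range values for
#' tabular regression at 10^4 rows; [tune_guideboost()] searches the bounds
#' in [default_bounds()].
#'
#' @param learning_rate Shrinkage per boosting round, > 0.
#' @param max_depth Maximum tree depth.
#' @param max_bin Maximum histogram bins per feature.
#' @param num_leaves Maximum leaves per tree.
#' @param feature_fraction Fraction of features sampled per tree, in (0, 1].
#' @param bagging_fraction Fraction of rows sampled per tree, in (0, 1].
#' @return A named list of class `guideboost_params`.
#' @export
hyper_params <- function(learning_rate = 0.05, max_depth = 8, max_bin = 255,
                         num_leaves = 63, feature_fraction = 1.0,
                         bagging_fraction = 1.0) {
  stopifnot(learning_rate > 0, max_depth >= 1, max_bin >= 2, num_leaves >= 2,
    feature_fraction > 0, feature_fraction <= 1,
    bagging_fraction > 0, bagging_fraction <= 1)
  structure(list(
    learning_rate = learning_rate, max_depth = as.integer(max_depth),
    max_bin = as.integer(max_bin), num_leaves = as.integer(num_leaves),
    feature_fraction = feature_fraction, bagging_fraction = bagging_fraction
  ), class = "guideboost_params")
}

#' Default hyperparameter search bounds
#'
#' Standard well-behaved ranges for ~10^4-row tabular regression:
#' `learning_rate` in \[0.005, 0.3\] on a log scale, `max_depth` in
#' \[3, 12\], `num_leaves` in \[8, 256\], `max_bin` in \[63, 511\], sampling
#' fractions in \[0.5, 1\]. All configurable.
#'
#' @return Named list of bound specifications for [bayesian_optimize()].
#' @export
default_bounds <- function() {
  list(
    learning_rate = list(lower = 0.005, upper = 0.3, log = TRUE),
    max_depth = list(lower = 3, upper = 12, integer = TRUE),
    num_leaves = list(lower = 8, upper = 256, integer = TRUE),
    max_bin = list(lower = 63, upper = 511, integer = TRUE),
    feature_fraction = list(lower = 0.5, upper = 1),
    bagging_fraction = list(lower = 0.5, upper = 1)
  )
}

#' Cross-validation configuration
#'
#' Ten folds, a fixed fold seed (so the identical fold assignment is reused
#' for every hyperparameter evaluation), a 7,000-tree ceiling and early
#' stopping after 10 non-improving rounds on the held-out fold, under mean
#' squared error.
#'
#' @param k_folds Number of folds.
#' @param fold_seed Seed fixing the fold assignment.
#' @param max_trees Boosting-round ceiling per fit.
#' @param early_stopping_rounds Patience on the validation fold.
#' @return A list of class `guideboost_cv_config`.
#' @export
cv_config <- function(k_folds = 10, fold_seed = 2024, max_trees = 7000,
                      early_stopping_rounds = 10) {
  stopifnot(k_folds >= 2, max_trees >= 1, early_stopping_rounds >= 1)
  structure(list(k_folds = as.integer(k_folds),
    fold_seed = as.integer(fold_seed), max_trees = as.integer(max_trees),
    early_stopping_rounds = as.integer(early_stopping_rounds)),
    class = "guideboost_cv_config")
}

#' Deterministic near-equal fold assignment
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Seed; the same seed always yields the same assignment.
#' @return Integer vector in `1..k` of length `n`; fold sizes differ by at
#'   most 1.
#' @export
make_folds <- function(n, k, seed) {
  if (n < k) {
    rlang::abort("Need n >= k to form folds.",
      class = "guideboost_param_error")
  }
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# Encode a schema-conformant feature table as a double matrix with 0-based
# integer codes for categorical columns, plus xgboost feature types.
encode_features <- function(features, schema = feature_schema()) {
  missing <- setdiff(schema$feature, names(features))
  if (length(missing)) {
    rlang::abort(paste0("Feature table is missing column(s): ",
      paste(utils::head(missing, 5), collapse = ", ")),
      class = "guideboost_schema_error")
  }
  cols <- vector("list", nrow(schema))
  unseen <- character(0)
  for (i in seq_len(nrow(schema))) {
    v <- features[[schema$feature[i]]]
    if (schema$type[i] == "categorical") {
      lev <- schema$levels[[i]]
      f <- factor(as.character(v), levels = lev)
      if (anyNA(f) && !anyNA(v)) unseen <- c(unseen, schema$feature[i])
      cols[[i]] <- as.double(f) - 1
    } else {
      cols[[i]] <- as.double(v)
    }
  }
  if (length(unseen)) {
    rlang::warn(paste0(
      "Unseen categorical level(s) in: ", paste(unseen, collapse = ", "),
      "; encoded as missing (learner default-direction fallback)."),
      class = "guideboost_unseen_level_warning")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- schema$feature
  list(X = X, types = ifelse(schema$type == "categorical", "c", "q"))
}

xgb_param_list <- function(params, base_score, seed) {
  list(
    objective = "reg:squarederror", tree_method = "hist",
    eta = params$learning_rate, max_depth = params$max_depth,
    max_bin = params$max_bin, max_leaves = params$num_leaves,
    colsample_bytree = params$feature_fraction,
    subsample = params$bagging_fraction,
    lambda = 0, nthread = 1, seed = seed, base_score = base_score
  )
}

#' Cross-validated evaluation of one hyperparameter combination
#'
#' For each fold, fits on the remaining folds with early stopping monitored
#' on the held-out fold (RMSE), then scores the held-out predictions at the
#' best iteration. Returns fold-averaged validation MSE and Spearman
#' correlation plus the per-fold best tree counts (consumed by
#' [train_final()]).
#'
#' @param features Schema-conformant feature table (149 columns).
#' @param y Observed efficiencies, one per row.
#' @param params [hyper_params()].
#' @param cv [cv_config()].
#' @param schema Feature schema; default [feature_schema()].
#' @param seed Training seed passed to the learner (row/column subsampling).
#' @return List with `mean_mse`, `mean_spearman`, `best_iterations`, and a
#'   per-fold tibble `folds`.
#' @export
cv_evaluate <- function(features, y, params = hyper_params(),
                        cv = cv_config(), schema = feature_schema(),
                        seed = 1L) {
  if (length(y) != nrow(features)) {
    rlang::abort("`y` must have one value per feature row.",
      class = "guideboost_schema_error")
  }
  enc <- encode_features(features, schema)
  fold <- make_folds(length(y), cv$k_folds, cv$fold_seed)
  base <- mean(y)
  res <- lapply(seq_len(cv$k_folds), function(f) {
    tr <- fold != f
    stopifnot(!any(which(!tr) %in% which(tr))) # no train/validation leak
    dtr <- xgboost::xgb.DMatrix(enc$X[tr, , drop = FALSE], label = y[tr],
      feature_types = enc$types)
    dva <- xgboost::xgb.DMatrix(enc$X[!tr, , drop = FALSE], label = y[!tr],
      feature_types = enc$types)
    bst <- xgboost::xgb.train(
      params = xgb_param_list(params, base_score = mean(y[tr]), seed = seed),
      data = dtr, nrounds = cv$max_trees, evals = list(val = dva),
      early_stopping_rounds = cv$early_stopping_rounds, verbose = 0
    )
    log <- attributes(bst)$evaluation_log
    best <- which.min(log$val_rmse)
    pred <- predict(bst, dva, iterationrange = c(1, best))
    yv <- y[!tr]
    rho <- tryCatch(spearman_cor(pred, yv),
      guideboost_degenerate_error = function(e) NA_real_)
    list(best = best, mse = mean((pred - yv)^2), rho = rho)
  })
  folds <- tibble::tibble(
    fold = seq_len(cv$k_folds),
    best_iteration = vapply(res, `[[`, numeric(1), "best"),
    mse = vapply(res, `[[`, numeric(1), "mse"),
    spearman = vapply(res, `[[`, numeric(1), "rho")
  )
  list(
    mean_mse = mean(folds$mse),
    mean_spearman = if (all(is.na(folds$spearman))) NA_real_
      else mean(folds$spearman, na.rm = TRUE),
    best_iterations = folds$best_iteration,
    folds = folds
  )
}

#' Train the final model on all rows
#'
#' Refits on the entire training set using the tree count obtained in
#' cross-validation: `round(mean(best_iterations))` (round-half-even). The
#' model stores its feature schema, the training grand mean as `base_value`,
#' and full provenance (hyperparameters, seeds, thermodynamic settings).
#'
#' @inheritParams cv_evaluate
#' @param best_iterations Per-fold best tree counts from [cv_evaluate()].
#' @param provenance Optional named list merged into the stored provenance
#'   (e.g. scaffold sequence, Tm settings, folding-engine name).
#' @return Object of class `guideboost_fit`.
#' @export
train_final <- function(features, y, params = hyper_params(),
                        best_iterations, schema = feature_schema(),
                        seed = 1L, provenance = list()) {
  if (length(best_iterations) == 0L) {
    rlang::abort("`best_iterations` must be non-empty.",
      class = "guideboost_param_error")
  }
  n_trees <- as.integer(round(mean(best_iterations)))
  enc <- encode_features(features, schema)
  base <- mean(y)
  booster <- NULL
  if (n_trees >= 1L) {
    dtr <- xgboost::xgb.DMatrix(enc$X, label = y, feature_types = enc$types)
    booster <- xgboost::xgb.train(
      params = xgb_param_list(params, base_score = base, seed = seed),
      data = dtr, nrounds = n_trees, verbose = 0
    )
  }
  structure(list(
    booster = booster,
    schema = schema,
    base_value = base,
    n_trees = n_trees,
    params = params,
    cache = new.env(parent = emptyenv()),
    provenance = c(list(
      train_seed = seed,
      best_iterations = as.numeric(best_iterations),
      n_train = length(y),
      backend = paste0("xgboost ", as.character(utils::packageVersion("xgboost")))
    ), provenance)
  ), class = "guideboost_fit")
}

#' Fit a model with fixed hyperparameters (CV for the tree count, then final fit)
#'
#' Convenience wrapper: runs [cv_evaluate()] to determine the per-fold best
#' tree counts under early stopping, then [train_final()] on all rows.
#'
#' @inheritParams cv_evaluate
#' @param provenance See [train_final()].
#' @return A `guideboost_fit`, with the CV summary attached as the `cv`
#'   element of its provenance.
#' @export
fit_guideboost <- function(features, y, params = hyper_params(),
                           cv = cv_config(), schema = feature_schema(),
                           seed = 1L, provenance = list()) {
  cvres <- cv_evaluate(features, y, params = params, cv = cv,
    schema = schema, seed = seed)
  fit <- train_final(features, y, params = params,
    best_iterations = cvres$best_iterations, schema = schema, seed = seed,
    provenance = c(provenance, list(
      fold_seed = cv$fold_seed,
      cv_mean_mse = cvres$mean_mse,
      cv_mean_spearman = cvres$mean_spearman
    )))
  fit
}

#' Predict cleavage efficiency for featurized guides
#'
#' Predictions are assembled in double precision as the training grand mean
#' plus the sum of the parsed per-tree leaf values along each row's leaf
#' assignment, so they agree exactly with the additive contribution
#' decomposition of [predict_contributions()].
#'
#' @param object A `guideboost_fit`.
#' @param newdata Feature table conforming to the model's schema.
#' @param ... Unused.
#' @return Numeric vector of predicted efficiencies, one per row.
#' @export
predict.guideboost_fit <- function(object, newdata, ...) {
  enc <- encode_features(newdata, object$schema)
  if (is.null(object$booster)) {
    return(rep(object$base_value, nrow(enc$X)))
  }
  trees <- parse_trees(object)
  leaves <- predict_leaf_ids(object, enc)
  pred <- rep(object$base_value, nrow(enc$X))
  for (t in seq_along(trees)) {
    leaf_vals <- trees[[t]]
    lv <- stats::setNames(leaf_vals$value[leaf_vals$leaf],
      leaf_vals$nodeid[leaf_vals$leaf])
    pred <- pred + lv[as.character(leaves[, t])]
  }
  unname(pred)
}

#' Featurize raw sequences and predict in one step
#'
#' @param object A `guideboost_fit`.
#' @param sequences Character vector of 30-mer expanded targets.
#' @param engine,scaffold,tm_params Thermodynamic settings; defaults as in
#'   [featurize_guides()].
#' @return Tibble with `sequence30` and `predicted` columns.
#' @export
predict_efficiency <- function(object, sequences, engine = rnafold_engine(),
                               scaffold = sp_cas9_scaffold(),
                               tm_params = tm_defaults()) {
  x <- validate_target(sequences)
  feats <- featurize(x, thermo_features(x, engine = engine,
    scaffold = scaffold, tm_params = tm_params))
  tibble::tibble(sequence30 = x, predicted = predict(object, feats))
}

#' @export
print.guideboost_fit <- function(x, ...) {
  cat(sprintf(
    "guideboost model: %d trees, %d features, base value %.4f (trained on %d guides)\n",
    x$n_trees, nrow(x$schema), x$base_value, x$provenance$n_train
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.guideboost_fit <- function(x, ...) {
  feature_importance(x)
}

#' @exportS3Method generics::glance
glance.guideboost_fit <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees,
    n_features = nrow(x$schema),
    base_value = x$base_value,
    n_train = x$provenance$n_train %||% NA_integer_,
    cv_mean_mse = x$provenance$cv_mean_mse %||% NA_real_,
    cv_mean_spearman = x$provenance$cv_mean_spearman %||% NA_real_
  )
}

#' Persist a trained model (text model file + JSON sidecar)
#'
#' The booster is written in the learner's JSON text format; schema, base
#' value, hyperparameters and provenance go to a `.sidecar.json` next to it.
#'
#' @param object A `guideboost_fit`.
#' @param path Output path for the model file (e.g. `model.json`).
#' @return `path`, invisibly.
#' @export
write_guideboost <- function(object, path) {
  sidecar <- list(
    base_value = object$base_value,
    n_trees = object$n_trees,
    params = unclass(object$params),
    provenance = object$provenance,
    schema = list(
      feature = object$schema$feature,
      type = object$schema$type,
      levels = object$schema$levels
    )
  )
  if (!is.null(object$booster)) {
    xgboost::xgb.save(object$booster, path)
  } else {
    writeLines("{}", path)
  }
  jsonlite::write_json(sidecar, paste0(path, ".sidecar.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model written by [write_guideboost()]
#'
#' @param path Path to the model file.
#' @return A `guideboost_fit`.
#' @export
read_guideboost <- function(path) {
  sc <- jsonlite::read_json(paste0(path, ".sidecar.json"),
    simplifyVector = TRUE)
  schema <- tibble::tibble(
    feature = sc$schema$feature,
    type = sc$schema$type,
    levels = lapply(sc$schema$levels, function(l) if (length(l)) l else NULL)
  )
  booster <- NULL
  if (sc$n_trees >= 1L) booster <- xgboost::xgb.load(path)
  structure(list(
    booster = booster, schema = schema, base_value = sc$base_value,
    n_trees = as.integer(sc$n_trees),
    cache = new.env(parent = emptyenv()),
    params = do.call(hyper_params, as.list(sc$params)),
    provenance = sc$provenance
  ), class = "guideboost_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
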