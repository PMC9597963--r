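# Parse the booster's JSON dump into one tidy node table per tree.
# Categorical splits carry the subset of category codes routed to the "yes"
# child; codes are translated back to the schema's level strings.
parse_trees <- function(object) {
  stopifnot(inherits(object, "guideboost_fit"))
  if (is.null(object$booster)) return(list())
  if (!is.null(object$cache) && !is.null(object$cache$trees)) {
    return(object$cache$trees)
  }
  dump <- xgboost::xgb.dump(object$booster, dump_format = "json",
    with_stats = TRUE)
  trees <- jsonlite::fromJSON(paste(dump, collapse = "\n"),
    simplifyVector = FALSE)
  schema <- object$schema
  parsed <- lapply(seq_along(trees), function(t) {
    acc <- list(nodeid = integer(), depth = integer(), leaf = logical(),
      feature = character(), split_type = character(), threshold = double(),
      categories = list(), yes = integer(), no = integer(),
      missing = integer(), gain = double(), cover = double(),
      value = double())
    push <- function(...) {
      vals <- list(...)
      for (nm in names(vals)) {
        acc[[nm]][length(acc[[nm]]) + 1L] <<- vals[[nm]]
      }
    }
    walk <- function(node, depth) {
      if (!is.null(node$leaf)) {
        push(nodeid = node$nodeid, depth = depth, leaf = TRUE,
          feature = NA_character_, split_type = NA_character_,
          threshold = NA_real_, categories = list(NULL),
          yes = NA_integer_, no = NA_integer_, missing = NA_integer_,
          gain = NA_real_, cover = node$cover, value = node$leaf)
        return(invisible())
      }
      categorical <- is.list(node$split_condition) ||
        length(node$split_condition) > 1L
      cats <- NULL
      thr <- NA_real_
      if (categorical) {
        codes <- unlist(node$split_condition)
        lev <- schema$levels[[match(node$split, schema$feature)]]
        cats <- lev[codes + 1L]
      } else {
        thr <- node$split_condition
      }
      push(nodeid = node$nodeid, depth = depth, leaf = FALSE,
        feature = node$split,
        split_type = if (categorical) "categorical" else "numeric",
        threshold = thr, categories = list(cats),
        yes = node$yes, no = node$no, missing = node$missing,
        gain = node$gain, cover = node$cover, value = NA_real_)
      for (child in node$children) walk(child, depth + 1L)
    }
    walk(trees[[t]], 0L)
    ord <- order(acc$nodeid)
    tb <- tibble::tibble(
      nodeid = acc$nodeid[ord], depth = acc$depth[ord],
      leaf = acc$leaf[ord], feature = acc$feature[ord],
      split_type = acc$split_type[ord], threshold = acc$threshold[ord],
      categories = acc$categories[ord], yes = acc$yes[ord],
      no = acc$no[ord], missing = acc$missing[ord], gain = acc$gain[ord],
      cover = acc$cover[ord], value = acc$value[ord]
    )
    tb
  })
  if (!is.null(object$cache)) object$cache$trees <- parsed
  parsed
}

#' Normalized gain feature importance
#'
#' Sums, over every split in every tree, the recorded improvement on the
#' squared-error objective attributable to each feature, and normalizes so
#' the fractions sum to 1. Categorical features are credited as whole
#' features (positions), not per level. Ordering is by descending gain with
#' a deterministic alphabetical tie-break.
#'
#' @param object A `guideboost_fit` with at least one split.
#' @return Tibble with columns `feature`, `gain`, `gain_fraction`, `rank`,
#'   `n_splits`. A model with zero splits yields an empty table with a
#'   warning.
#' @export
feature_importance <- function(object) {
  trees <- parse_trees(object)
  empty <- tibble::tibble(feature = character(), gain = numeric(),
    gain_fraction = numeric(), rank = integer(), n_splits = integer())
  if (length(trees) == 0L) {
    rlang::warn("Model contains no splits; importance table is empty.",
      class = "guideboost_empty_model_warning")
    return(empty)
  }
  nodes <- dplyr::bind_rows(trees)
  splits <- dplyr::filter(nodes, !.data$leaf)
  if (nrow(splits) == 0L) {
    rlang::warn("Model contains no splits; importance table is empty.",
      class = "guideboost_empty_model_warning")
    return(tibble::tibble(feature = character(), gain = numeric(),
      gain_fraction = numeric(), rank = integer(), n_splits = integer()))
  }
  splits |>
    dplyr::summarise(gain = sum(.data$gain), n_splits = dplyr::n(),
      .by = "feature") |>
    dplyr::mutate(gain_fraction = .data$gain / sum(.data$gain)) |>
    dplyr::arrange(dplyr::desc(.data$gain), .data$feature) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("feature", "gain", "gain_fraction", "rank", "n_splits")
}

# Double-precision node values of one parsed tree: cover-weighted
# aggregation of leaf values up the tree (the branch mean of the stage's
# boosting residuals).
node_values <- function(tree) {
  v <- stats::setNames(rep(NA_real_, nrow(tree)), tree$nodeid)
  w <- stats::setNames(rep(NA_real_, nrow(tree)), tree$nodeid)
  agg <- function(id) {
    key <- as.character(id)
    nd <- tree[tree$nodeid == id, ]
    if (nd$leaf) {
      v[key] <<- nd$value
      w[key] <<- nd$cover
    } else {
      agg(nd$yes)
      agg(nd$no)
      ya <- as.character(nd$yes)
      na <- as.character(nd$no)
      w[key] <<- w[ya] + w[na]
      v[key] <<- (v[ya] * w[ya] + v[na] * w[na]) / w[key]
    }
    invisible()
  }
  agg(0L)
  list(value = v, weight = w)
}

# For every leaf of a tree, the root-to-leaf list of (split feature, value
# increment); increments telescope exactly to the leaf value.
leaf_paths <- function(tree) {
  nv <- node_values(tree)$value
  paths <- list()
  walk <- function(id, acc_feat, acc_delta, parent_value) {
    nd <- tree[tree$nodeid == id, ]
    if (nd$leaf) {
      paths[[as.character(id)]] <<- list(
        feature = acc_feat,
        delta = acc_delta,
        leaf_value = nd$value
      )
      return(invisible())
    }
    for (child in c(nd$yes, nd$no)) {
      walk(child, c(acc_feat, nd$feature),
        c(acc_delta, nv[as.character(child)] - parent_value),
        nv[as.character(child)])
    }
    invisible()
  }
  # the root's (numerically ~0) aggregate is folded into the first step so
  # the per-tree contributions sum to the leaf value exactly
  walk(0L, character(0), numeric(0), 0)
  paths
}

# Leaf assignment matrix (n x n_trees) of nodeids reached by each row.
predict_leaf_ids <- function(object, enc) {
  dm <- xgboost::xgb.DMatrix(enc$X, feature_types = enc$types)
  m <- predict(object$booster, dm, predleaf = TRUE)
  matrix(as.integer(m), nrow = nrow(enc$X))
}

#' Per-prediction additive contribution breakdown
#'
#' Decomposes each prediction into the training grand mean (`base_value`)
#' plus one signed contribution per feature. The default attribution is
#' path-based: along each tree's root-to-leaf path, the change in branch
#' mean at every split is credited to the split feature and accumulated in
#' double precision, so the decomposition is exact:
#' `base_value + sum(contributions) == prediction` to machine precision.
#' `method = "native"` returns the learner's SHAP-style output instead
#' (float32; additivity then holds only to ~1e-5 on a 0--100 scale).
#'
#' @param object A `guideboost_fit`.
#' @param features Schema-conformant feature table.
#' @param method `"path"` (default) or `"native"`.
#' @return Long tibble with columns `.row`, `feature`, `contribution`,
#'   plus per-row `prediction` and `base_value` repeated for convenience;
#'   the attribution scheme is recorded in the `method` attribute.
#' @export
predict_contributions <- function(object, features,
                                  method = c("path", "native")) {
  method <- match.arg(method)
  enc <- encode_features(features, object$schema)
  n <- nrow(enc$X)
  feats <- object$schema$feature
  if (is.null(object$booster)) {
    contrib <- matrix(0, nrow = n, ncol = length(feats),
      dimnames = list(NULL, feats))
    pred <- rep(object$base_value, n)
  } else if (method == "native") {
    dm <- xgboost::xgb.DMatrix(enc$X, feature_types = enc$types)
    raw <- predict(object$booster, dm, predcontrib = TRUE)
    bias_col <- which(colnames(raw) %in% c("BIAS", "(Intercept)"))
    contrib <- raw[, -bias_col, drop = FALSE]
    pred <- as.numeric(predict(object$booster, dm))
  } else {
    trees <- parse_trees(object)
    leaves <- predict_leaf_ids(object, enc)
    contrib <- matrix(0, nrow = n, ncol = length(feats),
      dimnames = list(NULL, feats))
    pred <- rep(object$base_value, n)
    for (t in seq_along(trees)) {
      paths <- leaf_paths(trees[[t]])
      ids <- leaves[, t]
      for (leaf in unique(ids)) {
        rows <- which(ids == leaf)
        p <- paths[[as.character(leaf)]]
        for (s in seq_along(p$feature)) {
          contrib[rows, p$feature[s]] <- contrib[rows, p$feature[s]] +
            p$delta[s]
        }
        pred[rows] <- pred[rows] + p$leaf_value
      }
    }
  }
  out <- tibble::tibble(
    .row = rep(seq_len(n), each = ncol(contrib)),
    feature = rep(colnames(contrib), times = n),
    contribution = as.numeric(t(contrib)),
    prediction = rep(pred, each = ncol(contrib)),
    base_value = object$base_value
  )
  attr(out, "method") <- method
  out
}

#' Top contributions for one guide
#'
#' @param contributions Output of [predict_contributions()].
#' @param row Which guide (`.row` value).
#' @param n How many features to keep, by absolute contribution.
#' @return Tibble sorted by `abs(contribution)` descending.
#' @export
top_contributions <- function(contributions, row = 1L, n = 10L) {
  contributions |>
    dplyr::filter(.data$.row == row) |>
    dplyr::arrange(dplyr::desc(abs(.data$contribution))) |>
    dplyr::slice_head(n = n)
}

# Route rows of an encoded matrix through one parsed tree; returns the node
# id reached at each depth for every row (list: node id -> row indices).
route_rows <- function(tree, X) {
  membership <- list()
  assign_node <- function(nodeid, rows) {
    membership[[as.character(nodeid)]] <<- rows
    nd <- tree[tree$nodeid == nodeid, ]
    if (nd$leaf) return(invisible())
    x <- X[rows, nd$feature]
    if (nd$split_type == "categorical") {
      lev_codes <- match(nd$categories[[1]], attr(X, "schema_levels")[[nd$feature]]) - 1L
      go_yes <- x %in% lev_codes
    } else {
      go_yes <- x < nd$threshold
    }
    go_yes[is.na(go_yes)] <- nd$missing == nd$yes
    assign_node(nd$yes, rows[go_yes])
    assign_node(nd$no, rows[!go_yes])
  }
  assign_node(0L, seq_len(nrow(X)))
  membership
}

#' Export one regression tree with branch-mean internal values
#'
#' Returns the node table of the requested tree augmented with an
#' `internal_value` per node: the mean, among training rows reaching the
#' node, of the stage's boosting target. For the first tree (index 0) that
#' target is the observed efficiency itself, so the root's internal value is
#' the training grand mean; later trees fit residuals, so their roots sit at
#' 0 under squared-error loss. When training data are not supplied, internal
#' values fall back to cover-weighted aggregation of leaf values (an
#' approximation limited by the stored leaf precision).
#'
#' @param object A `guideboost_fit`.
#' @param tree_index 0-based tree index (matching the learner's numbering).
#' @param features,y The training feature table and efficiencies; optional
#'   but recommended for exact internal values.
#' @param max_depth Truncate the export below this depth (optional).
#' @return Tibble of nodes with split rules (threshold or category subset),
#'   gain, cover and `internal_value`.
#' @export
export_tree <- function(object, tree_index, features = NULL, y = NULL,
                        max_depth = NULL) {
  trees <- parse_trees(object)
  if (tree_index < 0 || tree_index >= length(trees)) {
    rlang::abort(sprintf("tree_index must be in [0, %d].",
      length(trees) - 1L), class = "guideboost_param_error")
  }
  tree <- trees[[tree_index + 1L]]
  if (!is.null(features) && !is.null(y)) {
    enc <- encode_features(features, object$schema)
    X <- enc$X
    lev <- stats::setNames(object$schema$levels, object$schema$feature)
    attr(X, "schema_levels") <- lev
    if (tree_index == 0L) {
      target <- y
    } else {
      dm <- xgboost::xgb.DMatrix(X, feature_types = enc$types)
      prior <- predict(object$booster, dm,
        iterationrange = c(1, tree_index))
      target <- y - prior
    }
    membership <- route_rows(tree, X)
    tree$internal_value <- vapply(tree$nodeid, function(id) {
      rows <- membership[[as.character(id)]]
      if (length(rows) == 0L) return(NA_real_)
      mean(target[rows])
    }, numeric(1))
  } else {
    # cover-weighted aggregation of leaf values; tree 0 is shifted to the
    # running-prediction scale (base + residual mean)
    nv <- node_values(tree)$value
    offset <- if (tree_index == 0L) object$base_value else 0
    tree$internal_value <- unname(nv[as.character(tree$nodeid)]) + offset
  }
  if (!is.null(max_depth)) tree <- tree[tree$depth <= max_depth, ]
  tree
}

#' Write a tree export as a Graphviz DOT file
#'
#' Internal nodes are rectangles labeled with the split rule (categorical
#' rules printed as `feature in {A, B, ...}`) and internal value; leaves are
#' ovals.
#'
#' @param tree Output of [export_tree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_dot <- function(tree, path) {
  esc <- function(s) gsub('"', '\\\\"', s)
  lines <- c("digraph tree {", "  node [fontname=\"Helvetica\"];")
  for (i in seq_len(nrow(tree))) {
    nd <- tree[i, ]
    if (nd$leaf) {
      lines <- c(lines, sprintf(
        "  n%d [shape=oval, label=\"value = %.4f\\ncover = %d\"];",
        nd$nodeid, nd$internal_value, as.integer(nd$cover)))
    } else {
      rule <- if (identical(nd$split_type, "categorical")) {
        sprintf("%s in {%s}", nd$feature,
          paste(nd$categories[[1]], collapse = ", "))
      } else {
        sprintf("%s < %.6g", nd$feature, nd$threshold)
      }
      lines <- c(lines, sprintf(
        "  n%d [shape=box, label=\"%s\\ninternal_value = %.4f\"];",
        nd$nodeid, esc(rule), nd$internal_value))
      if (nd$yes %in% tree$nodeid) {
        lines <- c(lines, sprintf("  n%d -> n%d [label=\"yes\"];",
          nd$nodeid, nd$yes))
      }
      if (nd$no %in% tree$nodeid) {
        lines <- c(lines, sprintf("  n%d -> n%d [label=\"no\"];",
          nd$nodeid, nd$no))
      }
    }
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
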