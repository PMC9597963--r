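#' Filter guides by read support
#'
#' Keeps guides with at least `threshold` reads; the number removed is
#' reported with a message. Mirrors the read-support filter applied to
#' screen replicates before averaging.
#'
#' @param data Data frame with columns `sequence30`, `efficiency`, `reads`.
#' @param threshold Minimum read count (inclusive); default 200.
#' @return Filtered tibble.
#' @export
filter_min_reads <- function(data, threshold = 200) {
  if (!"reads" %in% names(data)) {
    rlang::abort("`data` must have a `reads` column.",
      class = "guideboost_schema_error")
  }
  kept <- dplyr::filter(tibble::as_tibble(data), .data$reads >= threshold)
  rlang::inform(sprintf("filter_min_reads: removed %d of %d guides (< %s reads).",
    nrow(data) - nrow(kept), nrow(data), format(threshold)),
    class = "guideboost_filter_notice")
  kept
}

#' Average two replicate screens over their intersection
#'
#' Returns only guides present in both replicates, with efficiency equal to
#' the arithmetic mean of the two measurements.
#'
#' @param a,b Data frames keyed by `sequence30` with an `efficiency` column.
#' @return Tibble with columns `sequence30`, `efficiency`.
#' @export
average_replicates <- function(a, b) {
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(a), "sequence30", eff_a = "efficiency"),
    dplyr::select(tibble::as_tibble(b), "sequence30", eff_b = "efficiency"),
    by = "sequence30"
  ) |>
    dplyr::mutate(efficiency = (.data$eff_a + .data$eff_b) / 2) |>
    dplyr::select("sequence30", "efficiency")
}

#' Fit the cross-study affine normalization model
#'
#' Ordinary least squares of the reference-scale efficiency on the
#' source-scale efficiency over guides measured in both studies. The fitted
#' model rescales the source study onto the reference scale via
#' `reference = intercept + slope * source`.
#'
#' @param pairs Data frame with columns `source` and `reference`.
#' @return Object of class `guideboost_norm` with elements `intercept`,
#'   `slope`, `n_overlap`, `residual_sd` and the underlying `lm` fit.
#' @examples
#' fit_normalization(data.frame(source = c(10, 20, 30), reference = c(20, 40, 60)))
#' @export
fit_normalization <- function(pairs) {
  if (!all(c("source", "reference") %in% names(pairs))) {
    rlang::abort("`pairs` must have columns `source` and `reference`.",
      class = "guideboost_schema_error")
  }
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 2L || stats::sd(pairs$source) == 0) {
    rlang::abort(
      "Normalization needs >= 2 overlap pairs with non-constant source values.",
      class = "guideboost_degenerate_fit_error")
  }
  fit <- stats::lm(reference ~ source, data = pairs)
  structure(
    list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      n_overlap = nrow(pairs),
      residual_sd = stats::sigma(fit),
      fit = fit
    ),
    class = "guideboost_norm"
  )
}

#' @export
print.guideboost_norm <- function(x, ...) {
  cat(sprintf(
    "Affine normalization: reference = %.4f + %.4f * source (n = %d, residual SD = %.3f)\n",
    x$intercept, x$slope, x$n_overlap, x$residual_sd
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.guideboost_norm <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(summary(x$fit)$coefficients[, "Std. Error"])
  )
}

#' @exportS3Method generics::glance
glance.guideboost_norm <- function(x, ...) {
  tibble::tibble(
    n_overlap = x$n_overlap,
    residual_sd = x$residual_sd,
    r.squared = summary(x$fit)$r.squared
  )
}

#' Apply an affine normalization model to a dataset
#'
#' @param data Data frame with an `efficiency` column.
#' @param model A `guideboost_norm` fit from [fit_normalization()].
#' @return `data` with efficiency mapped to the reference scale.
#' @export
apply_normalization <- function(data, model) {
  stopifnot(inherits(model, "guideboost_norm"))
  dplyr::mutate(tibble::as_tibble(data),
    efficiency = model$intercept + model$slope * .data$efficiency)
}

#' Merge datasets, averaging duplicated guides
#'
#' Union of all guides across the inputs (which must already share a common
#' efficiency scale); guides present in more than one dataset get the
#' unweighted arithmetic mean of their efficiencies. Order-invariant.
#'
#' @param ... Data frames keyed by `sequence30` with an `efficiency` column,
#'   or a single list of them.
#' @return Tibble with unique `sequence30` keys.
#' @export
merge_average_duplicates <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  dplyr::bind_rows(lapply(dots, function(d) {
    dplyr::select(tibble::as_tibble(d), "sequence30", "efficiency")
  })) |>
    dplyr::summarise(efficiency = mean(.data$efficiency),
      .by = "sequence30") |>
    dplyr::arrange(.data$sequence30)
}

#' Build a harmonized two-study training set
#'
#' Reproduces the cross-study training-set construction: (1) merge the first
#' study's train/test tables, averaging duplicates; (2) filter each replicate
#' day of the second study to guides with at least `read_threshold` reads and
#' average the day intersection; (3) fit an affine normalization on the
#' guides shared between the two studies and rescale the second study onto
#' the first study's scale; (4) merge, averaging shared guides. All
#' intermediate counts are recorded.
#'
#' @param study1_train,study1_test Data frames (`sequence30`, `efficiency`)
#'   on the reference scale.
#' @param study2_day8,study2_day10 Data frames (`sequence30`, `efficiency`,
#'   `reads`) on the source scale.
#' @param read_threshold Minimum reads per replicate day; default 200.
#' @return List of class `guideboost_training_set`: `data` (the combined
#'   tibble), `normalization` (the affine model), and `counts` (tibble of
#'   stage sizes: study1 merged, study2 unique, overlap, final unique).
#' @export
build_training_set <- function(study1_train, study1_test,
                               study2_day8, study2_day10,
                               read_threshold = 200) {
  study1 <- merge_average_duplicates(study1_train, study1_test)
  study2 <- average_replicates(
    filter_min_reads(study2_day8, read_threshold),
    filter_min_reads(study2_day10, read_threshold)
  )
  overlap <- dplyr::inner_join(
    dplyr::select(study2, "sequence30", source = "efficiency"),
    dplyr::select(study1, "sequence30", reference = "efficiency"),
    by = "sequence30"
  )
  norm <- fit_normalization(overlap)
  study2_rescaled <- apply_normalization(study2, norm)
  combined <- merge_average_duplicates(study1, study2_rescaled)
  structure(
    list(
      data = combined,
      normalization = norm,
      counts = tibble::tibble(
        stage = c("study1_merged", "study2_unique", "overlap", "final_unique"),
        n = c(nrow(study1), nrow(study2), nrow(overlap), nrow(combined))
      )
    ),
    class = "guideboost_training_set"
  )
}

#' @export
print.guideboost_training_set <- function(x, ...) {
  cat("Harmonized training set\n")
  print(x$counts)
  print(x$normalization)
  invisible(x)
}
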