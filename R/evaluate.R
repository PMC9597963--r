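#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), the standard
#' metric for ranking-oriented evaluation of efficiency predictors.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The correlation, in `[-1, 1]`.
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("`x` and `y` must have equal length.",
      class = "guideboost_param_error")
  }
  if (length(x) < 3L) {
    rlang::abort("Need at least 3 observations.",
      class = "guideboost_param_error")
  }
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    rlang::abort("Zero rank variance; correlation undefined.",
      class = "guideboost_degenerate_error")
  }
  stats::cor(x, y, method = "spearman")
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Tests whether `r_jk` and `r_jh` (both involving the shared variable j,
#' e.g. observed efficiency against two predictors k and h) differ, given
#' the correlation `r_kh` between the two non-shared variables, using
#' Steiger's (1980) Z2* statistic: Fisher-z difference scaled by the pooled
#' estimate of the covariance between the two correlations. Applied here to
#' Spearman correlations, as is common when comparing rank-based predictor
#' performance (approximate; noted in the output).
#'
#' @param r_jk,r_jh The two dependent correlations sharing variable j.
#' @param r_kh Correlation between variables k and h.
#' @param n Sample size (> 3).
#' @param two_sided Two-sided p-value (default); set `FALSE` for one-sided.
#' @return Tibble with columns `z`, `p`, `n`, and a `note` on the rank-based
#'   approximation.
#' @examples
#' steiger_test(0.5, 0.3, 0.4, 100)
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n, two_sided = TRUE) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) {
    rlang::abort("Correlations must be finite and within [-1, 1].",
      class = "guideboost_param_error")
  }
  if (any(abs(c(r_jk, r_jh)) == 1)) {
    rlang::abort("|r| = 1 makes the Fisher-z variance degenerate.",
      class = "guideboost_degenerate_error")
  }
  if (n <= 3) {
    rlang::abort("Need n > 3.", class = "guideboost_param_error")
  }
  rbar <- (r_jk + r_jh) / 2
  cov_bar <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  s_bar <- cov_bar / (1 - rbar^2)^2
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt(n - 3) / sqrt(2 - 2 * s_bar)
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
  tibble::tibble(z = z, p = p, n = as.integer(n),
    note = "Steiger Z2*; applied to rank correlations (approximate)")
}

#' Evaluate a model against a measured dataset
#'
#' Drops guides in `exclude` (e.g. all training sequences, to prevent
#' train/test overlap), optionally negates the observed scores (for
#' negative-selection dropout screens reported as log2 fold changes, where
#' lower means more active), featurizes, predicts, and reports the Spearman
#' correlation with the post-exclusion sample size.
#'
#' @param object A `guideboost_fit`.
#' @param data Data frame with `sequence30` and `efficiency` columns.
#' @param reverse_scores Negate observed scores before correlating.
#' @param exclude Character vector of 30-mers to drop (default none).
#' @param engine,scaffold,tm_params Thermodynamic settings used to
#'   featurize; must match the model's training configuration.
#' @return Tibble with columns `n_used`, `spearman`.
#' @export
evaluate_dataset <- function(object, data, reverse_scores = FALSE,
                             exclude = character(0),
                             engine = rnafold_engine(),
                             scaffold = sp_cas9_scaffold(),
                             tm_params = tm_defaults()) {
  keep <- !(data$sequence30 %in% exclude)
  data <- tibble::as_tibble(data)[keep, ]
  if (nrow(data) < 3L) {
    rlang::abort("Fewer than 3 guides remain after exclusion.",
      class = "guideboost_insufficient_data_error")
  }
  obs <- data$efficiency
  if (reverse_scores) obs <- -obs
  pred <- predict_efficiency(object, data$sequence30, engine = engine,
    scaffold = scaffold, tm_params = tm_params)$predicted
  tibble::tibble(n_used = nrow(data), spearman = spearman_cor(pred, obs))
}

#' Compare two predictors on a shared dataset
#'
#' Computes both predictors' Spearman correlations with the observed
#' efficiency, the correlation between the two prediction vectors, and
#' Steiger's dependent-correlation test of the difference.
#'
#' @param observed Observed efficiencies.
#' @param pred_a,pred_b The two prediction vectors.
#' @param two_sided See [steiger_test()].
#' @return Tibble with `r_a`, `r_b`, `r_ab`, `n`, `z`, `p`.
#' @export
compare_predictors <- function(observed, pred_a, pred_b, two_sided = TRUE) {
  r_a <- spearman_cor(observed, pred_a)
  r_b <- spearman_cor(observed, pred_b)
  r_ab <- spearman_cor(pred_a, pred_b)
  st <- steiger_test(r_a, r_b, r_ab, length(observed), two_sided = two_sided)
  tibble::tibble(r_a = r_a, r_b = r_b, r_ab = r_ab,
    n = length(observed), z = st$z, p = st$p)
}
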