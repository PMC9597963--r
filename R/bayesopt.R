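# Gaussian-process machinery for Bayesian hyperparameter optimization.
# Search runs in the unit hypercube; integer and log-scaled dimensions are
# decoded only when calling the objective. Squared-exponential kernel with
# the length-scale chosen by marginal likelihood over a fixed grid.

sq_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

gp_fit <- function(X, y, lengthscales = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                   nugget = 1e-6) {
  m <- length(y)
  mu <- mean(y)
  sc <- stats::sd(y)
  if (!is.finite(sc) || sc == 0) sc <- 1
  z <- (y - mu) / sc
  D2 <- sq_dist(X, X)
  best <- NULL
  for (ell in lengthscales) {
    K <- exp(-0.5 * D2 / ell^2) + diag(nugget, m)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) next
    alpha <- backsolve(L, forwardsolve(t(L), z))
    logml <- -0.5 * sum(z * alpha) - sum(log(diag(L))) - 0.5 * m * log(2 * pi)
    if (is.null(best) || logml > best$logml) {
      best <- list(ell = ell, L = L, alpha = alpha, logml = logml)
    }
  }
  if (is.null(best)) {
    rlang::abort("Gaussian-process fit failed at every length-scale.",
      class = "guideboost_optimization_error")
  }
  c(best, list(X = X, mu = mu, sc = sc, z = z))
}

gp_predict <- function(gp, Xnew) {
  Ks <- exp(-0.5 * sq_dist(gp$X, Xnew) / gp$ell^2)
  mu_z <- drop(crossprod(Ks, gp$alpha))
  v <- forwardsolve(t(gp$L), Ks)
  var_z <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$sc * mu_z, sd = gp$sc * sqrt(var_z),
    mean_z = mu_z, sd_z = sqrt(var_z))
}

decode_point <- function(u, bounds) {
  out <- list()
  for (i in seq_along(bounds)) {
    b <- bounds[[i]]
    lo <- b$lower
    hi <- b$upper
    v <- if (isTRUE(b$log)) exp(log(lo) + u[i] * (log(hi) - log(lo)))
      else lo + u[i] * (hi - lo)
    if (isTRUE(b$integer)) v <- as.integer(round(v))
    out[[names(bounds)[i]]] <- v
  }
  out
}

#' Bayesian optimization of a black-box objective
#'
#' Maximizes `objective` over a bounded box: `n_init` space-filling random
#' points followed by `n_iter` rounds guided by a Gaussian-process surrogate
#' with the expected-improvement acquisition (maximized over a random
#' candidate set each round). Integer dimensions are rounded, log-scaled
#' dimensions are searched multiplicatively. A failing objective evaluation
#' is recorded as failed and the search continues; if every evaluation
#' fails the search errors.
#'
#' @param objective Function taking a named list of parameter values and
#'   returning a single finite score (higher is better).
#' @param bounds Named list; each element a list with `lower`, `upper`, and
#'   optional flags `log` and `integer`.
#' @param n_init Number of initial random evaluations.
#' @param n_iter Number of surrogate-guided rounds.
#' @param seed Seed making the whole search deterministic.
#' @param n_candidates Random candidates scored by the acquisition per round.
#' @param xi Exploration margin in the expected-improvement criterion.
#' @return List with `best_params` (named list), `best_score`, and `trace`
#'   (a tibble with one row per evaluation).
#' @examples
#' res <- bayesian_optimize(function(p) -(p$x - 2)^2,
#'   bounds = list(x = list(lower = 0, upper = 5)), n_init = 5, n_iter = 10,
#'   seed = 1)
#' res$best_params$x
#' @export
bayesian_optimize <- function(objective, bounds, n_init = 10, n_iter = 100,
                              seed = 1L, n_candidates = 500, xi = 0.01) {
  stopifnot(length(bounds) >= 1, n_init >= 1, n_iter >= 0)
  d <- length(bounds)
  withr::with_seed(seed, {
    U <- matrix(stats::runif(n_init * d), ncol = d)
    scores <- rep(NA_real_, n_init)
    notes <- rep(NA_character_, n_init)
    eval_point <- function(u) {
      p <- decode_point(u, bounds)
      tryCatch({
        s <- objective(p)
        if (!is.numeric(s) || length(s) != 1L || !is.finite(s)) {
          stop("objective must return one finite number")
        }
        list(score = s, note = NA_character_)
      }, error = function(e) list(score = NA_real_,
        note = conditionMessage(e)))
    }
    for (i in seq_len(n_init)) {
      r <- eval_point(U[i, ])
      scores[i] <- r$score
      notes[i] <- r$note
    }
    for (j in seq_len(n_iter)) {
      ok <- !is.na(scores)
      if (!any(ok)) break
      cand <- matrix(stats::runif(n_candidates * d), ncol = d)
      if (sum(ok) >= 2L) {
        gp <- gp_fit(U[ok, , drop = FALSE], scores[ok])
        pr <- gp_predict(gp, cand)
        best_z <- max(gp$z)
        imp <- pr$mean_z - best_z - xi
        zz <- imp / pr$sd_z
        ei <- imp * stats::pnorm(zz) + pr$sd_z * stats::dnorm(zz)
        pick <- which.max(ei)
      } else {
        pick <- 1L
      }
      r <- eval_point(cand[pick, ])
      U <- rbind(U, cand[pick, ])
      scores <- c(scores, r$score)
      notes <- c(notes, r$note)
    }
    if (all(is.na(scores))) {
      rlang::abort("All objective evaluations failed.",
        class = "guideboost_optimization_error")
    }
    params_tbl <- dplyr::bind_rows(lapply(seq_len(nrow(U)), function(i) {
      tibble::as_tibble(decode_point(U[i, ], bounds))
    }))
    trace <- dplyr::bind_cols(
      tibble::tibble(
        eval = seq_len(nrow(U)),
        phase = c(rep("init", n_init), rep("bo", nrow(U) - n_init))
      ),
      params_tbl,
      tibble::tibble(score = scores, failed = is.na(scores), note = notes)
    )
    best <- which.max(scores)
    list(
      best_params = decode_point(U[best, ], bounds),
      best_score = scores[best],
      trace = trace
    )
  })
}

#' Bayesian hyperparameter tuning of the efficiency model
#'
#' Wraps [bayesian_optimize()] around the cross-validated objective
#' (negative mean validation MSE, so higher is better) with the identical
#' fold assignment reused at every evaluation.
#'
#' @inheritParams cv_evaluate
#' @param bounds Search bounds; default [default_bounds()].
#' @param n_init,n_iter Search budget (defaults 10 random + 100 guided
#'   rounds).
#' @param seed Seed for the search and the learner.
#' @return List with `best_params` (a [hyper_params()] object), `best_cv`
#'   (the [cv_evaluate()] result at the optimum) and the search `trace`.
#' @export
tune_guideboost <- function(features, y, bounds = default_bounds(),
                            cv = cv_config(), schema = feature_schema(),
                            n_init = 10, n_iter = 100, seed = 1L) {
  objective <- function(p) {
    res <- cv_evaluate(features, y, params = do.call(hyper_params, p),
      cv = cv, schema = schema, seed = seed)
    -res$mean_mse
  }
  opt <- bayesian_optimize(objective, bounds, n_init = n_init,
    n_iter = n_iter, seed = seed)
  best_params <- do.call(hyper_params, opt$best_params)
  best_cv <- cv_evaluate(features, y, params = best_params, cv = cv,
    schema = schema, seed = seed)
  list(best_params = best_params, best_cv = best_cv, trace = opt$trace)
}
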