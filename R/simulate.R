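#' Configuration for the synthetic screen generator
#'
#' Defines the planted structure of simulated lentiviral-library screens:
#' an additive efficiency signal on the indel-percent scale (baseline plus
#' poly-T penalty, a quadratic GC-content optimum, and positional
#' mono-/dinucleotide category effects near the 3' end of the spacer),
#' Gaussian measurement noise, clipping to the score bounds, an affine link
#' between paired screens, and a heavy-tailed read-count distribution so a
#' realistic fraction of guides falls below the read filter.
#'
#' Default effect sizes mirror the magnitudes seen in real screens: about
#' -10 score units per poly-T run unit beyond length 2 (the observed spread
#' between no-poly-T, TTT and TTTT+ guide groups), dinucleotide effects at
#' spacer positions 19/18 of a few score units, and noise SD 10.
#'
#' @param n_guides Guides per screen.
#' @param baseline Baseline efficiency (score units, 0--100 scale).
#' @param polyt_penalty Score change per unit of `max_polyT` above 2
#'   (negative: Pol III termination depresses expression).
#' @param gc_center,gc_curvature Quadratic GC optimum:
#'   `gc_curvature * (gc - gc_center)^2` is added (curvature negative).
#' @param di19_effects,di18_effects,mono20_effects Named category-offset
#'   vectors for the planted positional effects.
#' @param noise_sd Gaussian noise SD (score units).
#' @param bounds Clipping bounds of the observed score.
#' @param affine `c(intercept, slope)` linking the paired screen's scale to
#'   the true signal.
#' @param overlap Guides shared between paired screens.
#' @param read_mu,read_size Negative-binomial read-count parameters.
#' @param seed Seed controlling every random draw.
#' @return A list of class `guideboost_generator_config`.
#' @export
generator_config <- function(n_guides = 5000, baseline = 45,
                             polyt_penalty = -10,
                             gc_center = 0.55, gc_curvature = -80,
                             di19_effects = default_di19_effects(),
                             di18_effects = default_di19_effects() * 0.6,
                             mono20_effects = c(A = -1, C = 0.5, G = 3, T = -2.5),
                             noise_sd = 10, bounds = c(0, 100),
                             affine = c(intercept = 5, slope = 0.8),
                             overlap = 49, read_mu = 400, read_size = 1.5,
                             seed = 1L) {
  stopifnot(n_guides > 0, noise_sd >= 0, bounds[1] < bounds[2],
    overlap <= n_guides)
  structure(as.list(environment()), class = "guideboost_generator_config")
}

#' Default planted dinucleotide effects at spacer position 19
#'
#' Purine-rich dinucleotides ending the spacer are favored, reproducing the
#' qualitative pattern that the 3' spacer end dominates position-specific
#' importance.
#'
#' @return Named numeric vector over the 16 dinucleotides (score units).
#' @export
default_di19_effects <- function() {
  c(AA = -3, AC = 2, AG = 2.5, AT = -4, CA = 0.5, CC = -1, CG = 1, CT = -2,
    GA = 5, GC = 3.5, GG = 4, GT = 2, TA = -2.5, TC = -1.5, TG = 1.5,
    TT = -5)
}

#' Draw random valid expanded targets
#'
#' Uniform nucleotides at every position except labels 22--23, which are
#' fixed to GG so every draw passes [validate_target()].
#'
#' @param n Number of targets.
#' @return Character vector of 30-mers.
#' @export
random_targets <- function(n) {
  m <- matrix(sample(DNA_BASES, 30 * n, replace = TRUE), nrow = n)
  m[, 26] <- "G"
  m[, 27] <- "G"
  apply(m, 1, paste, collapse = "")
}

# Noiseless planted signal for a set of targets under a config.
planted_signal <- function(x, cfg) {
  pt <- polyt_features(x)
  gc <- gc_content(x)
  di19 <- target_region(x, "19", "20")
  di18 <- target_region(x, "18", "19")
  mono20 <- target_region(x, "20", "20")
  cfg$baseline +
    cfg$polyt_penalty * pmax(0, pt$max_polyT - 2) +
    cfg$gc_curvature * (gc - cfg$gc_center)^2 +
    cfg$di19_effects[di19] +
    cfg$di18_effects[di18] +
    cfg$mono20_effects[mono20]
}

#' Simulate one efficiency screen
#'
#' Draws random targets, computes the noiseless planted signal, adds
#' Gaussian noise and clips to the score bounds. The clipping fraction is
#' reported with a message (planted signal stays analytically known away
#' from the bounds). Both the observed efficiency and the noiseless signal
#' are returned so recovery can be measured against ground truth.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with columns `sequence30`, `signal`, `efficiency`.
#' @export
simulate_dataset <- function(cfg = generator_config()) {
  withr::with_seed(cfg$seed, {
    x <- random_targets(cfg$n_guides)
    signal <- unname(planted_signal(x, cfg))
    eff <- signal + stats::rnorm(cfg$n_guides, 0, cfg$noise_sd)
    clipped <- eff < cfg$bounds[1] | eff > cfg$bounds[2]
    rlang::inform(sprintf("simulate_dataset: clipped %.1f%% of scores.",
      100 * mean(clipped)), class = "guideboost_clip_notice")
    tibble::tibble(
      sequence30 = x, signal = signal,
      efficiency = pmin(pmax(eff, cfg$bounds[1]), cfg$bounds[2])
    )
  })
}

#' Simulate two overlapping screens on different affine scales
#'
#' Emulates the harmonization setting: screen A reports the signal on its
#' native scale; screen B reports `intercept + slope * signal` plus noise,
#' measured on two replicate days with negative-binomial read counts (so a
#' configurable fraction of guides falls below a read filter). The first
#' `overlap` guides of screen A are also present in screen B by
#' construction.
#'
#' @param cfg A [generator_config()].
#' @return List with elements `screen_a` (`sequence30`, `signal`,
#'   `efficiency`), `day8` and `day10` (`sequence30`, `efficiency`,
#'   `reads`), and `shared` (the planted overlap keys).
#' @export
simulate_paired_screens <- function(cfg = generator_config()) {
  withr::with_seed(cfg$seed, {
    n <- cfg$n_guides
    x_a <- random_targets(n)
    x_b <- c(x_a[seq_len(cfg$overlap)], random_targets(n - cfg$overlap))
    sig_a <- unname(planted_signal(x_a, cfg))
    sig_b <- unname(planted_signal(x_b, cfg))
    screen_a <- tibble::tibble(
      sequence30 = x_a, signal = sig_a,
      efficiency = pmin(pmax(sig_a + stats::rnorm(n, 0, cfg$noise_sd),
        cfg$bounds[1]), cfg$bounds[2])
    )
    day <- function() {
      tibble::tibble(
        sequence30 = x_b,
        efficiency = cfg$affine[["intercept"]] +
          cfg$affine[["slope"]] * sig_b +
          stats::rnorm(n, 0, cfg$noise_sd * cfg$affine[["slope"]]),
        reads = stats::rnbinom(n, mu = cfg$read_mu, size = cfg$read_size)
      )
    }
    list(screen_a = screen_a, day8 = day(), day10 = day(),
      shared = x_a[seq_len(cfg$overlap)])
  })
}
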