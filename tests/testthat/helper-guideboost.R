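# Shared fixtures and independent oracles for the test suite.

# Two published example 30-mers (upstream 4 nt | spacer 20 nt | PAM | 3 nt)
FIG_A <- "GTCTGCCATCTCTGATGGATGTGATGGGCA"
FIG_B <- "GGGGGGACTGTATCGACGCTGAATTGGGGG"

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(strsplit(s, ""), function(ch) {
    paste(rev(ch), collapse = "")
  }, character(1)))
}

# Independent nearest-neighbor Tm oracle: full 16-stack table typed out
# explicitly (no complement expansion), straight-line arithmetic.
oracle_tm <- function(s, na_molar = 0.05, ct_molar = 2.5e-7) {
  dh <- c(
    AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
    CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
    GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
    TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9
  )
  ds <- c(
    AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
    CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
    GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
    TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2
  )
  ch <- strsplit(s, "")[[1]]
  H <- 0
  S <- 0
  for (i in seq_len(length(ch) - 1)) {
    st <- paste0(ch[i], ch[i + 1])
    H <- H + dh[[st]]
    S <- S + ds[[st]]
  }
  for (end in c(ch[1], ch[length(ch)])) {
    if (end %in% c("G", "C")) {
      H <- H + 0.1
      S <- S - 2.8
    } else {
      H <- H + 2.3
      S <- S + 4.1
    }
  }
  S <- S + 0.368 * (length(ch) - 1) * log(na_molar)
  1000 * H / (S + 1.987 * log(ct_molar / 4)) - 273.15
}

# Memoized small synthetic screen + trained model shared across test files.
.fixtures <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixtures$small)) {
    sim <- quiet(simulate_dataset(generator_config(n_guides = 600, seed = 11)))
    feats <- quiet(featurize(
      sim$sequence30,
      thermo_features(sim$sequence30, engine = stub_engine())
    ))
    fit <- quiet(fit_guideboost(
      feats, sim$efficiency,
      params = hyper_params(learning_rate = 0.1),
      cv = cv_config(k_folds = 4, max_trees = 250), seed = 1
    ))
    .fixtures$small <- list(sim = sim, feats = feats, fit = fit)
  }
  .fixtures$small
}

stub_featurize <- function(x) {
  quiet(featurize(x, thermo_features(x, engine = stub_engine())))
}
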