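# SantaLucia (1998) unified DNA/DNA nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); stacks read 5'->3' on the top strand.
NN_UNIFIED <- local({
  dH <- c(
    AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
    GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0
  )
  dS <- c(
    AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4, CT = -21.0,
    GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9
  )
  # complete by duplex symmetry: stack XY == reverse complement stack
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
    collapse = ""))
  for (s in names(dH)) {
    r <- rc(s)
    if (!r %in% names(dH)) {
      dH[r] <- dH[[s]]
      dS[r] <- dS[[s]]
    }
  }
  list(
    dH = dH, dS = dS,
    init_gc = c(dH = 0.1, dS = -2.8), # per duplex end closed by G*C
    init_at = c(dH = 2.3, dS = 4.1)   # per duplex end closed by A*T
  )
})

#' Default nearest-neighbor Tm parameters
#'
#' Unified DNA/DNA nearest-neighbor thermodynamics with monovalent-salt
#' entropy correction (`0.368 * (N - 1) * ln[Na+]` cal/(mol K)) and the
#' two-state duplex formula `Tm = dH / (dS + R ln(Ct / 4)) - 273.15` for
#' non-self-complementary duplexes. Defaults: 50 mM Na+, 250 nM total strand
#' concentration. All values are recorded in trained-model provenance.
#'
#' @param na_molar Monovalent cation concentration, mol/L.
#' @param ct_molar Total strand concentration, mol/L.
#' @return List of settings consumed by [melting_temperature()].
#' @export
tm_defaults <- function(na_molar = 0.05, ct_molar = 2.5e-7) {
  list(method = "nearest_neighbor", table = "unified_1998",
    na_molar = na_molar, ct_molar = ct_molar)
}

#' Nearest-neighbor DNA duplex melting temperature
#'
#' Sums stacking enthalpies/entropies over adjacent base pairs plus terminal
#' initiation terms, applies the salt entropy correction, and converts to a
#' two-state melting temperature in degrees Celsius. Sensitive to base order,
#' not just composition, which is the point of using region-specific Tm as a
#' guide-activity feature.
#'
#' @param x Character vector of DNA sequences (length >= 2 each).
#' @param params Parameter set from [tm_defaults()].
#' @return Numeric vector of melting temperatures (degrees C).
#' @examples
#' melting_temperature(c("ATATATATAT", "GCGCGCGCGC"))
#' @export
melting_temperature <- function(x, params = tm_defaults()) {
  if (!is.character(x)) {
    rlang::abort("`x` must be a character vector.",
      class = "guideboost_type_error")
  }
  x <- toupper(x)
  if (any(nchar(x) < 2L)) {
    rlang::abort("Tm requires sequences of length >= 2.",
      class = "guideboost_param_error")
  }
  if (any(grepl("[^ACGT]", x))) {
    rlang::abort("Tm requires DNA sequences over {A, C, G, T}.",
      class = "guideboost_alphabet_error")
  }
  R <- 1.987 # cal/(mol K)
  vapply(x, function(s) {
    n <- nchar(s)
    stacks <- substring(s, 1:(n - 1L), 2:n)
    dH <- sum(NN_UNIFIED$dH[stacks])
    dS <- sum(NN_UNIFIED$dS[stacks])
    for (end in c(substr(s, 1L, 1L), substr(s, n, n))) {
      init <- if (end %in% c("G", "C")) NN_UNIFIED$init_gc else NN_UNIFIED$init_at
      dH <- dH + init[["dH"]]
      dS <- dS + init[["dS"]]
    }
    dS <- dS + 0.368 * (n - 1L) * log(params$na_molar)
    1000 * dH / (dS + R * log(params$ct_molar / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Region-specific melting temperature features
#'
#' Four melting temperatures over fixed spacer regions (position labels):
#' Tm1 over 1--21 (the 20-nt spacer plus the variable PAM nucleotide), Tm2
#' over 1--4, Tm3 over 5--12, Tm4 over 16--20.
#'
#' @param x Validated 30-mer sequences.
#' @param params See [tm_defaults()].
#' @return Tibble with columns `Tm1`--`Tm4`.
#' @export
tm_features <- function(x, params = tm_defaults()) {
  regions <- list(Tm1 = c("1", "21"), Tm2 = c("1", "4"),
    Tm3 = c("5", "12"), Tm4 = c("16", "20"))
  tibble::as_tibble(lapply(regions, function(r) {
    melting_temperature(target_region(x, r[1], r[2]), params = params)
  }))
}

#' Canonical SpCas9 sgRNA scaffold (81 nt)
#'
#' The constant guide segment appended to the spacer for full-guide folding:
#' the wild-type S. pyogenes sgRNA scaffold followed by the U6 poly-U
#' terminator, 81 nt total. Override via the `scaffold` argument of
#' [featurize_guides()] / [free_energy_features()]; the scaffold actually
#' used is recorded in model provenance.
#'
#' @return An 81-character RNA string.
#' @export
sp_cas9_scaffold <- function() {
  s <- paste0(
    "GUUUUAGAGCUAGAAAUAGCAAGUUAAAAUAAGGCUAGUCCGUUAUCAACUUGAAAAAGUGG",
    "CACCGAGUCGGUGCUUUUU"
  )
  stopifnot(nchar(s) == 81L)
  s
}

#' RNAfold folding engine
#'
#' Wraps the ViennaRNA `RNAfold` executable as a batched minimum-free-energy
#' engine: all sequences are folded in one subprocess call, and the
#' `structure (energy)` output lines are parsed exactly.
#'
#' @param path Executable name or path (default `"RNAfold"` on `PATH`).
#' @param temperature Folding temperature in degrees C (default 37).
#' @return A function `f(sequences) -> numeric` returning MFE in kcal/mol,
#'   with attributes `engine` and `temperature` for provenance.
#' @export
rnafold_engine <- function(path = "RNAfold", temperature = 37) {
  f <- function(seqs) {
    if (Sys.which(path) == "") {
      rlang::abort(sprintf(
        "Folding engine '%s' not found on PATH; configure another engine or install ViennaRNA.",
        path
      ), class = "guideboost_engine_error")
    }
    infile <- tempfile("fold", fileext = ".seq")
    on.exit(unlink(infile))
    writeLines(seqs, infile)
    args <- c("--noPS")
    if (temperature != 37) args <- c(args, paste0("--temp=", temperature))
    out <- suppressWarnings(system2(path, args, stdout = TRUE, stdin = infile))
    if (!is.null(attr(out, "status"))) {
      rlang::abort(sprintf("Engine '%s' exited with status %d.", path,
        attr(out, "status")), class = "guideboost_engine_error")
    }
    m <- regmatches(out, regexpr("\\(\\s*(-?[0-9]+\\.[0-9]+)\\)\\s*$", out))
    e <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    if (length(e) != length(seqs)) {
      rlang::abort("Engine output could not be parsed for every sequence.",
        class = "guideboost_engine_error")
    }
    e
  }
  structure(f, engine = "rnafold", temperature = temperature)
}

#' Deterministic stub folding engine
#'
#' Arithmetic stand-in engine for environments without an external folding
#' program: returns a reproducible, sequence-determined non-positive value.
#' Not a physical free energy; exists to exercise the engine-pluggability
#' contract and keep pipelines runnable and deterministic.
#'
#' @return A function `f(sequences) -> numeric` (values in `[-8, 0]`).
#' @export
stub_engine <- function() {
  f <- function(seqs) {
    vapply(seqs, function(s) {
      h <- sum(utf8ToInt(s) * seq_len(nchar(s))) %% 801L
      -h / 100
    }, numeric(1), USE.NAMES = FALSE)
  }
  structure(f, engine = "stub", temperature = 37)
}

#' Minimum free energy of RNA secondary structure
#'
#' DNA input (T) is transcribed to RNA (U) with a notice. The engine is
#' responsible for the fold; by MFE convention a sequence with no favorable
#' structure scores 0 and all values are <= 0.
#'
#' @param x Character vector of RNA (or DNA) sequences.
#' @param engine Folding engine (see [rnafold_engine()], [stub_engine()]).
#' @return Numeric vector of free energies, kcal/mol.
#' @export
mfe <- function(x, engine = rnafold_engine()) {
  if (!is.character(x) || length(x) == 0L || any(nchar(x) == 0L)) {
    rlang::abort("`x` must be non-empty sequences.",
      class = "guideboost_param_error")
  }
  x <- toupper(x)
  if (any(grepl("T", x))) {
    rlang::inform("Transcribing DNA input: T -> U.",
      class = "guideboost_transcribe_notice")
    x <- chartr("T", "U", x)
  }
  if (any(grepl("[^ACGU]", x))) {
    rlang::abort("Sequences must be RNA over {A, C, G, U} after transcription.",
      class = "guideboost_alphabet_error")
  }
  e <- engine(x)
  if (any(!is.finite(e))) {
    rlang::abort("Folding engine returned non-finite energies.",
      class = "guideboost_engine_error")
  }
  e
}

#' Spacer and full-guide folding free energies
#'
#' `dG_spacer` folds the transcribed 20-nt spacer alone; `dG_full` folds the
#' spacer joined to the 81-nt scaffold (101 nt), approximating the folding
#' propensity of the full sgRNA. Both depend only on the spacer (and the
#' fixed scaffold), never on the genomic context or PAM.
#'
#' @param x Validated 30-mer sequences.
#' @param scaffold Scaffold RNA string, default [sp_cas9_scaffold()].
#' @param engine Folding engine.
#' @return Tibble with columns `dG_spacer`, `dG_full`.
#' @export
free_energy_features <- function(x, scaffold = sp_cas9_scaffold(),
                                 engine = rnafold_engine()) {
  spacer <- chartr("T", "U", target_region(x, "1", "20"))
  tibble::tibble(
    dG_spacer = mfe(spacer, engine = engine),
    dG_full = mfe(paste0(spacer, scaffold), engine = engine)
  )
}

#' All six thermodynamic features
#'
#' @inheritParams free_energy_features
#' @param tm_params See [tm_defaults()].
#' @return Tibble with columns `Tm1`--`Tm4`, `dG_spacer`, `dG_full`.
#' @export
thermo_features <- function(x, engine = rnafold_engine(),
                            scaffold = sp_cas9_scaffold(),
                            tm_params = tm_defaults()) {
  dplyr::bind_cols(
    tm_features(x, params = tm_params),
    free_energy_features(x, scaffold = scaffold, engine = engine)
  )
}
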