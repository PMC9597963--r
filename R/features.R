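#' @importFrom rlang .data
NULL

# fixed k-mer vocabularies in lexicographic order
kmer_vocab <- function(k) {
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, g[, rev(seq_len(k)), drop = FALSE])
}

# start labels of the 28 retained adjacent position pairs (pair (22,23),
# the static GG of the PAM, is excluded); a pair is named by its start label
di_start_offsets <- function() setdiff(1:29, 26L)

di_feature_names <- function() paste0("di", target_labels()[di_start_offsets()])

mono_feature_names <- function() {
  paste0("mono", target_labels()[setdiff(1:30, c(26L, 27L))])
}

#' Count overlapping k-mers in 30-mer targets
#'
#' Raw counts of all overlapping windows of length `k` over the whole 30-mer,
#' in fixed lexicographic k-mer order. Counts sum to `30 - k + 1` per
#' sequence. Set `proportions = TRUE` to divide by the window count
#' (monotone-equivalent for tree splits; counts are the default because they
#' are exactly testable integers).
#'
#' @param x Validated 30-mer sequences (see [validate_target()]).
#' @param k Window length: 1, 2 or 3.
#' @param proportions Return window proportions instead of counts.
#' @return Integer (or double) matrix, one row per sequence, `4^k` named
#'   columns.
#' @examples
#' kmer_counts("GTCTGCCATCTCTGATGGATGTGATGGGCA", 1)
#' @export
kmer_counts <- function(x, k, proportions = FALSE) {
  if (!(length(k) == 1L && k %in% 1:3)) {
    rlang::abort("`k` must be 1, 2 or 3.", class = "guideboost_param_error")
  }
  vocab <- kmer_vocab(k)
  n <- length(x)
  counts <- matrix(0L, nrow = n, ncol = length(vocab),
    dimnames = list(NULL, vocab))
  width <- nchar(x)
  for (s in seq_len(max(width) - k + 1L)) {
    code <- match(substr(x, s, s + k - 1L), vocab)
    ok <- !is.na(code) & (s + k - 1L) <= width
    idx <- cbind(which(ok), code[ok])
    counts[idx] <- counts[idx] + 1L
  }
  if (proportions) counts / (width - k + 1L) else counts
}

#' GC content of the expanded target
#'
#' @inheritParams kmer_counts
#' @return Numeric vector: (G count + C count) / 30, in `[0, 1]`.
#' @examples
#' gc_content("GTCTGCCATCTCTGATGGATGTGATGGGCA")
#' @export
gc_content <- function(x) {
  k1 <- kmer_counts(x, 1)
  unname((k1[, "G"] + k1[, "C"]) / nchar(x))
}

#' Poly-T segment features
#'
#' A poly-T segment is a contiguous stretch of 3 or more Ts -- an RNA Pol III
#' termination signal that depresses U6-driven guide expression.
#' `n_polyT` counts the maximal T-runs of length >= 3; `max_polyT` is the
#' length of the longest maximal T-run, reported unconditionally (so values
#' 1 or 2 are possible when no true poly-T segment exists). Set
#' `zero_short_runs = TRUE` to report 0 instead for runs shorter than 3.
#'
#' @inheritParams kmer_counts
#' @param zero_short_runs Report `max_polyT = 0` when the longest T-run is
#'   shorter than 3.
#' @return Tibble with integer columns `n_polyT` and `max_polyT`.
#' @examples
#' polyt_features("GTTTTCCATCTCTGATGGATGTGATGGGCA")
#' @export
polyt_features <- function(x, zero_short_runs = FALSE) {
  runs <- stringr::str_extract_all(x, "T+")
  run_len <- lapply(runs, nchar)
  n_seg <- vapply(run_len, function(l) sum(l >= 3L), integer(1))
  max_len <- vapply(run_len, function(l) if (length(l)) max(l) else 0L,
    integer(1))
  if (zero_short_runs) max_len[max_len < 3L] <- 0L
  tibble::tibble(n_polyT = n_seg, max_polyT = max_len)
}

#' Position-specific mononucleotides
#'
#' One categorical value (A/C/G/T) per position label in
#' `{-4..-1, 1..21, +1..+3}`. Labels 22 and 23 -- the static GG of the PAM --
#' are excluded, giving 28 features named `mono<label>`.
#'
#' @inheritParams kmer_counts
#' @return Tibble of 28 factor columns with levels A, C, G, T.
#' @export
positional_mononucleotides <- function(x) {
  offs <- setdiff(1:30, c(26L, 27L))
  cols <- lapply(offs, function(o) {
    factor(substr(x, o, o), levels = DNA_BASES)
  })
  names(cols) <- mono_feature_names()
  tibble::as_tibble(cols)
}

#' Position-specific dinucleotides
#'
#' One categorical value (16 levels) per adjacent position pair, keyed by the
#' start label: `di-1` spans labels (-1, 1) -- the boundary between upstream
#' context and spacer -- `di20` spans (20, 21) (spacer end and the variable
#' PAM nucleotide), `di23` spans (23, +1). The static pair (22, 23) is
#' excluded, giving 28 features named `di<start label>`.
#'
#' @inheritParams kmer_counts
#' @return Tibble of 28 factor columns with the 16 dinucleotide levels.
#' @export
positional_dinucleotides <- function(x) {
  vocab <- kmer_vocab(2)
  cols <- lapply(di_start_offsets(), function(o) {
    factor(substr(x, o, o + 1L), levels = vocab)
  })
  names(cols) <- di_feature_names()
  tibble::as_tibble(cols)
}

#' The 149-feature schema
#'
#' Fixed name/type/vocabulary table for the model's feature space: 93 numeric
#' features (GC content, 84 k-mer counts, 2 poly-T statistics, 4 melting
#' temperatures, 2 folding free energies) and 56 categorical features (28
#' position-specific mononucleotides + 28 dinucleotides). The schema is
#' persisted with every trained model and enforced at prediction time.
#'
#' @return Tibble with columns `feature`, `type` (`"numeric"` or
#'   `"categorical"`) and `levels` (list column; `NULL` for numeric features).
#' @examples
#' feature_schema()
#' @export
feature_schema <- function() {
  numeric_names <- c(
    "gc_content", kmer_vocab(1), kmer_vocab(2), kmer_vocab(3),
    "n_polyT", "max_polyT"
  )
  thermo_names <- c("Tm1", "Tm2", "Tm3", "Tm4", "dG_spacer", "dG_full")
  tibble::tibble(
    feature = c(numeric_names, mono_feature_names(), di_feature_names(),
      thermo_names),
    type = c(
      rep("numeric", length(numeric_names)),
      rep("categorical", 28L), rep("categorical", 28L),
      rep("numeric", length(thermo_names))
    ),
    levels = c(
      vector("list", length(numeric_names)),
      rep(list(DNA_BASES), 28L), rep(list(kmer_vocab(2)), 28L),
      vector("list", length(thermo_names))
    )
  )
}

#' Assemble the full 149-column feature table
#'
#' Deterministic, fixed-order assembly of all sequence-derived features plus
#' the six thermodynamic features. The heavy lifting for guides stored in a
#' data frame is done by [featurize_guides()]; this function operates on a
#' character vector of validated targets and a precomputed thermodynamic
#' block.
#'
#' @param x Validated 30-mer sequences.
#' @param thermo Tibble with columns `Tm1`--`Tm4`, `dG_spacer`, `dG_full`,
#'   one row per sequence (see [thermo_features()]).
#' @param kmer_proportions Use window proportions instead of counts for the
#'   k-mer block.
#' @param zero_short_polyt See [polyt_features()].
#' @return Tibble with 149 columns in schema order.
#' @export
featurize <- function(x, thermo, kmer_proportions = FALSE,
                      zero_short_polyt = FALSE) {
  need <- c("Tm1", "Tm2", "Tm3", "Tm4", "dG_spacer", "dG_full")
  if (!all(need %in% names(thermo)) || nrow(thermo) != length(x)) {
    rlang::abort(
      "`thermo` must have columns Tm1..Tm4, dG_spacer, dG_full and one row per sequence.",
      class = "guideboost_schema_error")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(gc_content = gc_content(x)),
    tibble::as_tibble(kmer_counts(x, 1, proportions = kmer_proportions)),
    tibble::as_tibble(kmer_counts(x, 2, proportions = kmer_proportions)),
    tibble::as_tibble(kmer_counts(x, 3, proportions = kmer_proportions)),
    polyt_features(x, zero_short_runs = zero_short_polyt),
    positional_mononucleotides(x),
    positional_dinucleotides(x),
    tibble::as_tibble(thermo[need])
  )
  stopifnot(identical(names(out), feature_schema()$feature))
  out
}

#' Featurize guides stored in a data frame
#'
#' Validates the sequences, computes the thermodynamic block (melting
#' temperatures and folding free energies) and assembles the 149-column
#' feature table. Non-feature columns of `data` are preserved in front of the
#' feature block, so the result pipes directly into model fitting.
#'
#' @param data Data frame with one row per guide.
#' @param sequence Name of the column holding the 30-mer expanded target
#'   sequences (default `sequence30`).
#' @param engine Folding engine for the free-energy features; default
#'   [rnafold_engine()]. Use [stub_engine()] for an external-tool-free run.
#' @param scaffold Scaffold RNA appended for full-guide folding; default
#'   [sp_cas9_scaffold()].
#' @param tm_params Nearest-neighbor parameter set; default [tm_defaults()].
#' @param pam_check,kmer_proportions,zero_short_polyt Passed through to
#'   [validate_target()], [kmer_counts()] and [polyt_features()].
#' @return `data` with 149 feature columns appended.
#' @examples
#' guides <- tibble::tibble(sequence30 = "GTCTGCCATCTCTGATGGATGTGATGGGCA")
#' featurize_guides(guides, engine = stub_engine())
#' @export
featurize_guides <- function(data, sequence = "sequence30",
                             engine = rnafold_engine(),
                             scaffold = sp_cas9_scaffold(),
                             tm_params = tm_defaults(),
                             pam_check = TRUE,
                             kmer_proportions = FALSE,
                             zero_short_polyt = FALSE) {
  if (!sequence %in% names(data)) {
    rlang::abort(sprintf("Column '%s' not found in `data`.", sequence),
      class = "guideboost_schema_error")
  }
  x <- validate_target(data[[sequence]], pam_check = pam_check)
  th <- thermo_features(x, engine = engine, scaffold = scaffold,
    tm_params = tm_params)
  dplyr::bind_cols(
    tibble::as_tibble(data),
    featurize(x, th, kmer_proportions = kmer_proportions,
      zero_short_polyt = zero_short_polyt)
  )
}
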