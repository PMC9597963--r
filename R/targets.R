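#' Position labels of the 30-nt expanded target
#'
#' The feature substrate is a 30-mer: 4 nt of upstream genomic context, the
#' 20-nt spacer (protospacer-matching sequence), the 3-nt NGG PAM, and 3 nt of
#' downstream context. Positions are labeled relative to the spacer start:
#' upstream context is `-4` to `-1`, spacer + PAM are `1` to `23` (the PAM
#' occupies 21--23), downstream context is `+1` to `+3`. There is no label 0.
#'
#' @return Character vector of length 30: the label for each sequence offset,
#'   in 5' to 3' order.
#' @examples
#' target_labels()
#' @export
target_labels <- function() {
  c(paste0("-", 4:1), as.character(1:23), paste0("+", 1:3))
}

#' Convert a position label to a 1-based sequence offset
#'
#' @param label Character vector of position labels (e.g. `"-4"`, `"1"`,
#'   `"21"`, `"+3"`).
#' @return Integer vector of 1-based offsets into the 30-mer.
#' @examples
#' label_offset(c("-4", "1", "20", "21", "+3"))
#' @export
label_offset <- function(label) {
  off <- match(as.character(label), target_labels())
  if (anyNA(off)) {
    rlang::abort(paste0(
      "Unknown position label(s): ",
      paste(unique(label[is.na(off)]), collapse = ", ")
    ), class = "guideboost_label_error")
  }
  off
}

DNA_BASES <- c("A", "C", "G", "T")

#' Validate and canonicalize expanded target sequences
#'
#' Checks that each sequence is exactly 30 nt, uses the DNA alphabet
#' (lowercase accepted and canonicalized to uppercase; `U` is rejected), and
#' carries `GG` at positions 22--23 (offsets 26--27), the invariant part of
#' the NGG PAM. Cpf1-style or other non-NGG inputs can be featurized for
#' exploratory use by disabling the PAM check.
#'
#' @param x Character vector of candidate 30-mers.
#' @param pam_check Require `GG` at labels 22--23 (default `TRUE`). Disabling
#'   the check is logged with a message.
#' @return The canonical uppercase sequences, invisibly classed as validated.
#' @examples
#' validate_target("GTCTGCCATCTCTGATGGATGTGATGGGCA")
#' @export
validate_target <- function(x, pam_check = TRUE) {
  if (!is.character(x)) {
    rlang::abort("`x` must be a character vector of sequences.",
      class = "guideboost_type_error")
  }
  x <- toupper(x)
  len <- nchar(x)
  if (any(len != 30L)) {
    i <- which(len != 30L)[1L]
    rlang::abort(sprintf(
      "Sequence %d has length %d; expanded targets must be exactly 30 nt.",
      i, len[i]
    ), class = "guideboost_length_error")
  }
  bad <- stringr::str_locate(x, "[^ACGT]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    rlang::abort(sprintf(
      "Sequence %d has a non-DNA character '%s' at offset %d (allowed: A, C, G, T).",
      i, substr(x[i], bad[i], bad[i]), bad[i]
    ), class = "guideboost_alphabet_error")
  }
  if (pam_check) {
    pam_gg <- substr(x, 26L, 27L)
    if (any(pam_gg != "GG")) {
      i <- which(pam_gg != "GG")[1L]
      rlang::abort(sprintf(
        "Sequence %d has '%s' at PAM positions 22-23; SpCas9 targets require NGG.",
        i, pam_gg[i]
      ), class = "guideboost_pam_error")
    }
  } else {
    rlang::inform("PAM check disabled; featurizing non-NGG sequences.",
      class = "guideboost_pam_notice")
  }
  x
}

#' Extract a region of the expanded target by position labels
#'
#' @param x Validated 30-mer sequences.
#' @param from,to Position labels delimiting the region (inclusive).
#' @return Character vector of subsequences.
#' @examples
#' target_region("GTCTGCCATCTCTGATGGATGTGATGGGCA", "1", "20") # the spacer
#' @export
target_region <- function(x, from, to) {
  substr(x, label_offset(from), label_offset(to))
}
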