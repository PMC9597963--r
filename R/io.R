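#' Read guide records from TSV, CSV or FASTA
#'
#' Tabular input is read with a configurable column mapping and normalized
#' to the canonical names `sequence30`, `efficiency`, `reads`; FASTA input
#' yields sequences only. Rows whose sequence fails 30-mer validation are
#' reported with their row numbers and dropped.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"fasta"`.
#' @param column_map Named list mapping canonical names to the file's
#'   column names, e.g. `list(sequence30 = "seq", efficiency = "indel_pct")`.
#' @param pam_check Passed to [validate_target()].
#' @return Tibble with `sequence30` and any mapped measurement columns.
#' @export
read_guides <- function(path, format = c("auto", "tsv", "csv", "fasta"),
                        column_map = list(), pam_check = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path),
      class = "guideboost_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", txt = "tsv",
      fa = "fasta", fasta = "fasta", fna = "fasta",
      rlang::abort(sprintf("Cannot infer format from extension '.%s'.", ext),
        class = "guideboost_io_error")
    )
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      rlang::abort("Reading FASTA requires the Biostrings package.",
        class = "guideboost_io_error")
    }
    seqs <- as.character(Biostrings::readDNAStringSet(path))
    tab <- tibble::tibble(sequence30 = unname(seqs))
  } else {
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    tab <- reader(path, show_col_types = FALSE, progress = FALSE)
    for (canonical in names(column_map)) {
      src <- column_map[[canonical]]
      if (!src %in% names(tab)) {
        rlang::abort(sprintf("Mapped column '%s' not found in %s.", src, path),
          class = "guideboost_io_error")
      }
      names(tab)[names(tab) == src] <- canonical
    }
    if (!"sequence30" %in% names(tab)) {
      rlang::abort("Input must provide a `sequence30` column (or map one).",
        class = "guideboost_io_error")
    }
    tab <- tibble::as_tibble(tab)
  }
  if (nrow(tab) == 0L) {
    rlang::warn(sprintf("%s contains no records.", path),
      class = "guideboost_empty_input_warning")
    return(tab)
  }
  ok <- vapply(tab$sequence30, function(s) {
    tryCatch({
      validate_target(s, pam_check = pam_check)
      TRUE
    }, error = function(e) FALSE, guideboost_pam_notice = function(c) TRUE)
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok)) {
    rlang::warn(sprintf("Dropping %d malformed row(s): %s", sum(!ok),
      paste(utils::head(which(!ok), 10), collapse = ", ")),
      class = "guideboost_malformed_rows_warning")
    tab <- tab[ok, ]
  }
  tab$sequence30 <- toupper(tab$sequence30)
  tab
}

#' Write a feature table as TSV with a machine-readable schema sidecar
#'
#' Tab-separated, UTF-8, '.' decimal, header row; categorical columns are
#' written as their 1--2 letter category strings. A JSON schema file (names,
#' types, category vocabularies) is written next to the table.
#'
#' @param features Feature table (possibly with leading id columns).
#' @param path Output TSV path.
#' @param schema Feature schema to record; default [feature_schema()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, schema = feature_schema()) {
  readr::write_tsv(features, path, progress = FALSE)
  jsonlite::write_json(
    list(feature = schema$feature, type = schema$type,
      levels = schema$levels),
    paste0(path, ".schema.json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}
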