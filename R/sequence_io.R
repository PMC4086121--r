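#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record) protein FASTA file into a tibble, one row per
#' record in file order. Residues are uppercased but *not* validated; run
#' [validate_sequences()] before feature extraction. The description is
#' everything after the first whitespace on the header line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`, `length`.
#' @seealso [validate_sequences()], [write_fasta()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp1 demo", "MKKRLLAVAA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) {
    stop("no sequences found in FASTA file: ", path, call. = FALSE)
  }
  headers <- names(aas)
  tibble::tibble(
    id          = sub("\\s.*$", "", headers),
    description = ifelse(grepl("\\s", headers),
                         sub("^\\S+\\s+", "", headers), ""),
    residues    = unname(toupper(as.character(aas)))
  ) |>
    dplyr::mutate(length = nchar(.data$residues))
}

#' Write sequences to a FASTA file
#'
#' @param sequences A tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  desc <- if ("description" %in% names(sequences)) {
    dplyr::coalesce(sequences$description, "")
  } else {
    rep("", nrow(sequences))
  }
  headers <- ifelse(nzchar(desc), paste(sequences$id, desc), sequences$id)
  aas <- Biostrings::AAStringSet(sequences$residues)
  names(aas) <- headers
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Validate sequences against the canonical amino-acid alphabet
#'
#' A sequence is valid iff every residue is one of the 20 canonical
#' one-letter codes. Ambiguity and non-standard codes (B, X, U, Z, J, O,
#' gaps, stops) invalidate the whole record; the reason reports the first
#' offending character and its 1-based position. Invalid records are the
#' ones later excluded (but reported) by [npp_run()].
#'
#' @param sequences A tibble as returned by [read_fasta()], or a character
#'   vector of residue strings.
#' @return The input tibble with logical column `valid` and character column
#'   `reason` (`NA` for valid records) appended.
#' @export
#' @examples
#' validate_sequences(tibble::tibble(id = c("a", "b"),
#'                                   residues = c("MKKRGA", "MKXRGA")))
validate_sequences <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(id = seq_along(sequences), residues = sequences)
  }
  stopifnot("residues" %in% names(sequences))
  check_one <- function(s) {
    if (is.na(s) || !nzchar(s)) {
      return("empty")
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% AA_ALPHABET))
    if (length(bad) == 0L) {
      return(NA_character_)
    }
    sprintf("non-canonical residue '%s' at position %d", chars[bad[1]], bad[1])
  }
  sequences |>
    dplyr::mutate(
      reason = purrr::map_chr(.data$residues, check_one),
      valid  = is.na(.data$reason)
    ) |>
    dplyr::relocate("valid", .before = "reason")
}

# Fixed column layout of the per-sequence results table.
RESULT_COLUMNS <- c(
  "id",
  "prob_random_forest", "prob_gradient_boosting", "prob_linear_svm",
  "prob_minimal_tree",
  "call_random_forest", "call_gradient_boosting", "call_linear_svm",
  "call_minimal_tree",
  "overall_call", "n_models_agreeing", "internal_score", "sp_call",
  "high_quality"
)

#' Write a prediction results table
#'
#' Writes per-sequence prediction records with a fixed, documented column
#' order: `id`, the four per-model probabilities, the four per-model calls,
#' `overall_call`, `n_models_agreeing`, `internal_score`, `sp_call`,
#' `high_quality`. An empty record set yields a header-only file.
#'
#' @param records A tibble of prediction records (see [npp_run()]).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  missing_cols <- setdiff(RESULT_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::select(records, dplyr::all_of(RESULT_COLUMNS))
  if (format == "tsv") {
    readr::write_tsv(out, path)
  } else {
    readr::write_csv(out, path)
  }
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @inheritParams write_results
#' @return A tibble with the fixed result columns.
#' @export
read_results <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  reader(path, show_col_types = FALSE)
}
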