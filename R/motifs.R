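#' Locate basic-residue cleavage motifs
#'
#' Scans a sequence for maximal runs of the basic residues K and R, the
#' canonical recognition sites of precursor-processing endopeptidases. Each
#' maximal run is classified once, so reported motifs never overlap:
#' a run of length 1 is a single basic site, a run of exactly 2 is one
#' dibasic motif (KK, KR, RK or RR) and a run of 3 or more is one tribasic
#' motif. Runs longer than 3 still count as a single tribasic motif.
#'
#' @param residues A single residue string (validated, uppercase).
#' @return A list of class `npp_motifs` with elements `single_basic`,
#'   `dibasic`, `tribasic` (integer vectors of 1-based run start positions),
#'   counts `n_single`, `n_dibasic`, `n_tribasic`, and `length`.
#' @seealso [internal_score()], [motif_table()]
#' @export
#' @examples
#' find_basic_sites("MAKKAARRGA")
find_basic_sites <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  is_basic <- chars %in% BASIC_RESIDUES
  r <- rle(is_basic)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  basic_start <- run_start[r$values]
  basic_len <- r$lengths[r$values]
  out <- list(
    single_basic = basic_start[basic_len == 1L],
    dibasic      = basic_start[basic_len == 2L],
    tribasic     = basic_start[basic_len >= 3L],
    run_lengths  = basic_len,
    length       = length(chars)
  )
  out$n_single <- length(out$single_basic)
  out$n_dibasic <- length(out$dibasic)
  out$n_tribasic <- length(out$tribasic)
  structure(out, class = "npp_motifs")
}

#' @export
print.npp_motifs <- function(x, ...) {
  cat("<npp_motifs> length", x$length, "aa:",
      x$n_single, "single,", x$n_dibasic, "dibasic,",
      x$n_tribasic, "tribasic\n")
  invisible(x)
}

#' Motif annotation as a BED-like table
#'
#' Tabulates motif spans in 1-based inclusive coordinates, the convention
#' of the sequence-graphics display.
#'
#' @param sequences A tibble with columns `id` and `residues`.
#' @return A tibble with columns `id`, `start`, `end`, `motif_class`
#'   (`single`/`dibasic`/`tribasic`).
#' @export
motif_table <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(id = seq_along(sequences), residues = sequences)
  }
  purrr::map2_dfr(sequences$id, sequences$residues, function(id, s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    is_basic <- chars %in% BASIC_RESIDUES
    r <- rle(is_basic)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    span <- tibble::tibble(
      id = rep(as.character(id), sum(r$values)),
      start = run_start[r$values],
      end = run_end[r$values],
      motif_class = dplyr::case_when(
        r$lengths[r$values] == 1L ~ "single",
        r$lengths[r$values] == 2L ~ "dibasic",
        TRUE ~ "tribasic"
      )
    )
    dplyr::arrange(span, .data$start)
  })
}

#' Internal Score: cleavage-motif density
#'
#' The Internal Score (IS) is the percentage of dibasic plus tribasic motifs
#' in the effective length of the protein, i.e. its length after removal of
#' a typical signal-peptide length (default 25 aa):
#' `IS = 100 * (n_dibasic + n_tribasic) / max(length - sp_trim, 1)`.
#' A high IS marks sequences rich in potential processing sites and is used
#' to rank positive predictions and select the high-quality subset.
#'
#' Motifs inside the first `sp_trim` residues are counted in the numerator
#' by default (only the denominator is trimmed); set
#' `count_nterm = FALSE` to exclude motifs starting within the trimmed
#' window. Sequences of `sp_trim` residues or fewer have their effective
#' length clamped to 1.
#'
#' @param residues A residue string, or a tibble with a `residues` column
#'   (then a vector of scores is returned).
#' @param sp_trim Signal-peptide length subtracted from the denominator
#'   (residues; default 25).
#' @param count_nterm Count motifs starting within the first `sp_trim`
#'   residues (default `TRUE`).
#' @return Internal Score(s) in percent.
#' @export
#' @examples
#' internal_score(strrep("AAAAAAAAAAAAAAAAAAAAAAKKA", 5))  # 5 dibasics, 125 aa
internal_score <- function(residues, sp_trim = 25, count_nterm = TRUE) {
  if (is.data.frame(residues)) {
    residues <- residues$residues
  }
  vapply(residues, function(s) {
    m <- find_basic_sites(s)
    starts <- c(m$dibasic, m$tribasic)
    if (!count_nterm) {
      starts <- starts[starts > sp_trim]
    }
    100 * length(starts) / max(m$length - sp_trim, 1)
  }, numeric(1), USE.NAMES = FALSE)
}
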