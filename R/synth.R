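# Synthetic sequence sets with the architecture the classifier assumes:
# positives mimic a neuropeptide precursor — an N-terminal hydrophobic
# signal-peptide-like segment, then several short peptide units each
# terminated by a dibasic (KK/KR/RK/RR) or tribasic flank — while
# negatives are background-composition sequences with low clustered-basic
# density (uniform-background, nuclear-like, globular-like classes).

#' Configuration of the synthetic sequence generator
#'
#' Defaults describe a "typical" precursor: a 25-aa signal peptide, 4-8
#' short repeated peptide units of 5-30 aa each (mature neuropeptides are
#' mostly 5-30 aa; the classic Allatostatin precursor carries 7 weak
#' repeats over ~370 aa), units flanked by dibasic motifs with an
#' occasional tribasic, and database-average background composition.
#'
#' @param n_sequences Number of sequences to generate.
#' @param seed Integer seed; same seed + config reproduce identical
#'   output.
#' @param length_range Target length range (aa) for negatives and for
#'   positive tail padding.
#' @param sp_length Signal-peptide-like segment length (default 25).
#' @param n_repeats_range Range of peptide-unit repeats per precursor.
#' @param repeat_length_range Range of unit lengths (aa).
#' @param flank_weights Named sampling weights over
#'   `KK`, `KR`, `RK`, `RR`, `tribasic`.
#' @param background Named composition over the 20 residues (defaults to
#'   database-average frequencies); must sum to 1.
#' @param negative_class `"uniform"` (background composition),
#'   `"nuclear"` (K/R-enriched overall but clustered runs suppressed) or
#'   `"globular"` (hydrophobic-shifted composition).
#' @param sanitize_negatives Remove *all* basic runs of length >= 2 from
#'   negatives (clean-oracle mode; default `FALSE`, spontaneous dibasics
#'   are allowed as realistic hardness).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_sequences = 200L, seed = 1L,
                         length_range = c(150L, 400L), sp_length = 25L,
                         n_repeats_range = c(4L, 8L),
                         repeat_length_range = c(5L, 30L),
                         flank_weights = c(KK = 0.30, KR = 0.25, RK = 0.20,
                                           RR = 0.15, tribasic = 0.10),
                         background = BACKGROUND_COMPOSITION,
                         negative_class = c("uniform", "nuclear", "globular"),
                         sanitize_negatives = FALSE) {
  negative_class <- match.arg(negative_class)
  stopifnot(
    n_sequences >= 1,
    length(length_range) == 2, diff(length_range) >= 0, length_range[1] > 0,
    sp_length >= 1,
    length(n_repeats_range) == 2, n_repeats_range[1] >= 0,
    diff(n_repeats_range) >= 0,
    length(repeat_length_range) == 2, repeat_length_range[1] >= 1,
    diff(repeat_length_range) >= 0,
    setequal(names(flank_weights), c("KK", "KR", "RK", "RR", "tribasic")),
    all(flank_weights >= 0), sum(flank_weights) > 0,
    setequal(names(background), AA_ALPHABET), all(background >= 0)
  )
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background composition must sum to 1", call. = FALSE)
  }
  structure(
    list(
      n_sequences = as.integer(n_sequences), seed = as.integer(seed),
      length_range = as.integer(length_range),
      sp_length = as.integer(sp_length),
      n_repeats_range = as.integer(n_repeats_range),
      repeat_length_range = as.integer(repeat_length_range),
      flank_weights = flank_weights / sum(flank_weights),
      background = background[AA_ALPHABET] / sum(background),
      negative_class = negative_class,
      sanitize_negatives = isTRUE(sanitize_negatives)
    ),
    class = "synth_config"
  )
}

# sample n residues from a composition, as a character vector
sample_bg <- function(n, composition) {
  if (n <= 0) return(character(0))
  sample(AA_ALPHABET, n, replace = TRUE, prob = composition)
}

NONBASIC <- setdiff(AA_ALPHABET, BASIC_RESIDUES)

# like sample_bg but basic residues excluded (used at flank boundaries so
# planted motifs stay maximal runs of the planted length)
sample_nonbasic <- function(n, composition) {
  if (n <= 0) return(character(0))
  p <- composition[NONBASIC]
  sample(NONBASIC, n, replace = TRUE, prob = p / sum(p))
}

# one SP-like N-terminal segment: Met start, short basic n-region,
# leucine-rich hydrophobic h-region, polar c-region
make_sp_segment <- function(sp_length) {
  core_len <- max(8L, min(12L, sp_length - 6L))
  n_region <- c("M", sample(BASIC_RESIDUES, 2L, replace = TRUE))
  h_region <- sample(c("L", "A", "V", "I", "F"), core_len, replace = TRUE,
                     prob = c(0.45, 0.25, 0.15, 0.1, 0.05))
  c_len <- max(0L, sp_length - length(n_region) - core_len)
  c_region <- sample(c("S", "T", "A", "G", "Q"), c_len, replace = TRUE)
  c(n_region, h_region, c_region)
}

#' Generate synthetic positive (precursor-like) sequences
#'
#' Each sequence is `SP segment | spacer | [unit | basic flank] x n | tail`.
#' Unit and spacer residues adjacent to a planted flank are forced
#' non-basic, so every planted flank is emitted as a maximal basic run of
#' exactly the planted class; spontaneous basic motifs elsewhere in units
#' are allowed.
#'
#' @param config A [synth_config()].
#' @return A list with `sequences` (tibble: `id`, `description`,
#'   `residues`, `length`) and `ground_truth` (tibble: `id`, `start`,
#'   `end`, `motif_class`, 1-based inclusive, matching [motif_table()]'s
#'   format).
#' @export
generate_positive <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    recs <- purrr::map(seq_len(config$n_sequences), function(i) {
      n_rep <- sample_range(config$n_repeats_range)
      parts <- list(make_sp_segment(config$sp_length))
      spacer_len <- sample_range(c(8L, 25L))
      spacer <- sample_bg(spacer_len, config$background)
      if (n_rep > 0 && spacer_len > 0) {
        spacer[spacer_len] <- sample_nonbasic(1L, config$background)
      }
      parts <- c(parts, list(spacer))
      truth <- list()
      pos_cursor <- config$sp_length + spacer_len
      for (r in seq_len(n_rep)) {
        unit_len <- sample_range(config$repeat_length_range)
        unit <- sample_bg(unit_len, config$background)
        unit[1] <- sample_nonbasic(1L, config$background)
        unit[unit_len] <- sample_nonbasic(1L, config$background)
        flank_kind <- sample(names(config$flank_weights), 1L,
                             prob = config$flank_weights)
        flank <- if (flank_kind == "tribasic") {
          sample(BASIC_RESIDUES, 3L, replace = TRUE)
        } else {
          strsplit(flank_kind, "", fixed = TRUE)[[1]]
        }
        start <- pos_cursor + unit_len + 1L
        truth[[r]] <- tibble::tibble(
          start = start, end = start + length(flank) - 1L,
          motif_class = if (flank_kind == "tribasic") "tribasic" else "dibasic"
        )
        parts <- c(parts, list(unit, flank))
        pos_cursor <- pos_cursor + unit_len + length(flank)
      }
      tail_len <- sample_range(c(5L, 40L))
      tail_seq <- sample_bg(tail_len, config$background)
      if (n_rep > 0 && tail_len > 0) {
        tail_seq[1] <- sample_nonbasic(1L, config$background)
      }
      parts <- c(parts, list(tail_seq))
      residues <- paste(unlist(parts), collapse = "")
      list(residues = residues,
           truth = dplyr::bind_rows(truth))
    })
    sequences <- tibble::tibble(
      id = sprintf("synthpos_%04d", seq_len(config$n_sequences)),
      description = "synthetic neuropeptide-precursor-like sequence",
      residues = purrr::map_chr(recs, "residues")
    ) |>
      dplyr::mutate(length = nchar(.data$residues))
    ground_truth <- purrr::map2_dfr(sequences$id, recs, function(id, r) {
      if (is.null(r$truth) || nrow(r$truth) == 0) return(NULL)
      dplyr::mutate(r$truth, id = id, .before = 1)
    })
    list(sequences = sequences, ground_truth = ground_truth)
  })
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

#' Generate synthetic negative sequences
#'
#' Background-sampled sequences of three classes: `"uniform"` draws from
#' the configured background composition; `"nuclear"` enriches K/R
#' overall (1.6x, renormalized) but rejection-samples any residue that
#' would extend a basic run to length >= 2, mimicking nuclear proteins'
#' dispersed basic residues; `"globular"` shifts composition toward
#' hydrophobic residues. With `sanitize_negatives = TRUE` every class
#' suppresses basic runs >= 2.
#'
#' @param config A [synth_config()].
#' @return A tibble of sequences (`id`, `description`, `residues`,
#'   `length`).
#' @export
generate_negative <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  comp <- switch(config$negative_class,
    uniform = config$background,
    nuclear = {
      p <- config$background
      p[BASIC_RESIDUES] <- p[BASIC_RESIDUES] * 1.6
      p / sum(p)
    },
    globular = {
      p <- config$background
      p[AA_CLASSES$hydrophobic] <- p[AA_CLASSES$hydrophobic] * 1.3
      p / sum(p)
    }
  )
  suppress_runs <- config$sanitize_negatives ||
    config$negative_class == "nuclear"
  withr::with_seed(config$seed + 1L, {
    residues <- purrr::map_chr(seq_len(config$n_sequences), function(i) {
      L <- sample_range(config$length_range)
      if (!suppress_runs) {
        return(paste(sample_bg(L, comp), collapse = ""))
      }
      chars <- character(L)
      for (j in seq_len(L)) {
        prev_basic <- j > 1L && chars[j - 1L] %in% BASIC_RESIDUES
        draw <- sample_bg(1L, comp)
        tries <- 0L
        while (prev_basic && draw %in% BASIC_RESIDUES) {
          tries <- tries + 1L
          if (tries > 50L) {
            stop("rejection sampling exceeded retry cap", call. = FALSE)
          }
          draw <- sample_bg(1L, comp)
        }
        chars[j] <- draw
      }
      paste(chars, collapse = "")
    })
    tibble::tibble(
      id = sprintf("synthneg_%s_%04d", config$negative_class,
                   seq_len(config$n_sequences)),
      description = paste0("synthetic negative (",
                           config$negative_class, ")"),
      residues = residues
    ) |>
      dplyr::mutate(length = nchar(.data$residues))
  })
}

#' Generate a labeled training set and its feature matrices
#'
#' Convenience wrapper: positives and negatives at the same size, plus
#' their extracted feature tables, ready for [npp_train()].
#'
#' @param n Sequences per class.
#' @param seed Integer seed.
#' @param negative_class Negative class passed to [synth_config()].
#' @param ... Further arguments to [synth_config()].
#' @return A list with `pos`, `neg` (sequence tibbles), `pos_features`,
#'   `neg_features` (feature tibbles) and `ground_truth`.
#' @export
synth_training_set <- function(n = 200L, seed = 1L,
                               negative_class = "uniform", ...) {
  cfg_pos <- synth_config(n_sequences = n, seed = seed, ...)
  cfg_neg <- synth_config(n_sequences = n, seed = seed + 10000L,
                          negative_class = negative_class, ...)
  pos <- generate_positive(cfg_pos)
  neg <- generate_negative(cfg_neg)
  list(
    pos = pos$sequences, neg = neg,
    pos_features = extract_features(pos$sequences),
    neg_features = extract_features(neg),
    ground_truth = pos$ground_truth
  )
}

#' Write a synthetic set to disk
#'
#' FASTA plus (for positives) the planted-motif ground truth as a
#' BED-like TSV in [motif_table()]'s format.
#'
#' @param set Output of [generate_positive()] or [generate_negative()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_synth <- function(set, dir, prefix = "synth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(set)) {
    write_fasta(set, file.path(dir, paste0(prefix, ".fasta")))
  } else {
    write_fasta(set$sequences, file.path(dir, paste0(prefix, ".fasta")))
    readr::write_tsv(set$ground_truth,
                     file.path(dir, paste0(prefix, "_ground_truth.tsv")))
  }
  invisible(dir)
}
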