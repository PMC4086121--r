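# End-to-end prediction: validate -> optional signal-peptide filter ->
# extract features -> score with the four-model ensemble -> rank by
# Internal Score -> partition into positive / high-quality sets.

#' Heuristic signal-peptide check
#'
#' Built-in fallback used when no external signal-peptide predictor is
#' configured: a sequence is flagged as carrying a putative signal peptide
#' when its first 25 residues contain a 7-residue window of mean
#' Kyte-Doolittle hydropathy >= `min_hydropathy` (a hydrophobic h-region)
#' positioned after at least one leading residue (the n-region).
#' This is a coarse architectural screen, *not* equivalent to a dedicated
#' signal-peptide predictor such as SignalP; use
#' `sp_filter = "external"` in [npp_run()] to plug one in.
#'
#' @param residues Residue string, or a tibble with a `residues` column
#'   (vectorized).
#' @param window Hydrophobic-core window length (default 7).
#' @param min_hydropathy Mean hydropathy cutoff for the core (default 1.0).
#' @return Logical flag(s).
#' @export
#' @examples
#' sp_heuristic("MKRLLLLLLLLLAVASSTTSADGKKR")  # SP-like N-terminus
#' sp_heuristic("MDDDDDDDDDDDDDDDDDDDDDDDDD")  # acidic N-terminus
sp_heuristic <- function(residues, window = 7L, min_hydropathy = 1.0) {
  if (is.data.frame(residues)) residues <- residues$residues
  vapply(residues, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(chars) < window + 1L) {
      return(FALSE)
    }
    nterm <- chars[seq_len(min(25L, length(chars)))]
    kd <- unname(KD_HYDROPATHY[nterm])
    # core windows start at position 2+ so an n-region residue precedes
    starts <- 2:(length(kd) - window + 1L)
    if (length(starts) < 1L || starts[1] > length(kd) - window + 1L) {
      return(FALSE)
    }
    any(vapply(starts, function(i) mean(kd[i:(i + window - 1L)]),
               numeric(1)) >= min_hydropathy)
  }, logical(1), USE.NAMES = FALSE)
}

#' Adapter for an external signal-peptide predictor
#'
#' Writes the sequences to a temporary FASTA file, substitutes its path
#' for `{fasta}` in the command template, runs the command and parses its
#' tabular output: non-comment lines of whitespace-separated fields where
#' the first field is the sequence id and one field is a yes/no verdict
#' (`YES`/`NO`, `Y`/`N`, `TRUE`/`FALSE`, `SP`/`OTHER`, case-insensitive).
#' Every input id must appear in the output.
#'
#' @param command_template Shell command containing the placeholder
#'   `{fasta}`.
#' @param sequences Tibble with `id` and `residues`.
#' @return Named logical vector of per-id signal-peptide flags, in input
#'   order.
#' @export
external_sp_adapter <- function(command_template, sequences) {
  stopifnot(grepl("{fasta}", command_template, fixed = TRUE))
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa), add = TRUE)
  write_fasta(sequences, fa)
  cmd <- sub("{fasta}", shQuote(fa), command_template, fixed = TRUE)
  exe <- strsplit(trimws(command_template), "\\s+")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    stop("external signal-peptide command not found: '", exe, "'",
         call. = FALSE)
  }
  out <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("external signal-peptide command failed (exit ", status, "):\n",
         paste(out, collapse = "\n"), call. = FALSE)
  }
  lines <- out[!grepl("^\\s*(#|$)", out)]
  yes_tokens <- c("yes", "y", "true", "sp", "1")
  no_tokens <- c("no", "n", "false", "other", "0")
  flags <- list()
  for (ln in lines) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    verdict <- tolower(fields[-1])
    hit <- verdict[verdict %in% c(yes_tokens, no_tokens)]
    if (length(fields) < 2L || length(hit) == 0L) {
      stop("unparseable line in external predictor output: '", ln, "'",
           call. = FALSE)
    }
    flags[[fields[1]]] <- hit[1] %in% yes_tokens
  }
  missing_ids <- setdiff(sequences$id, names(flags))
  if (length(missing_ids) > 0) {
    stop("external predictor output is missing ids: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  stats::setNames(unlist(flags)[as.character(sequences$id)], sequences$id)
}

#' Agreement histogram over the four classifiers
#'
#' @param records Scored prediction records (with `n_models_agreeing`).
#' @return A tibble with `n_models_agreeing` = 0..4 and `n` counts
#'   (summing to the number of records).
#' @export
agreement_partition <- function(records) {
  counts <- table(factor(records$n_models_agreeing, levels = 0:4))
  tibble::tibble(n_models_agreeing = 0:4, n = as.integer(counts))
}

#' Run the full NPP prediction pipeline
#'
#' Reads (or accepts) protein sequences, removes records with
#' non-canonical residues, optionally filters out sequences without a
#' predicted signal peptide, scores the survivors with the four-model
#' ensemble, computes the Internal Score of every scored sequence, and
#' returns records ranked by Internal Score (descending; ties broken by
#' the maximum model probability, then input order). A positive call with
#' `internal_score >= hq_threshold` is flagged high-quality.
#'
#' @param sequences Path to a FASTA file, or a tibble with `id` and
#'   `residues` columns.
#' @param bundle A trained `nppred_bundle`.
#' @param sp_filter `"off"` (default), `"heuristic"` ([sp_heuristic()]) or
#'   `"external"` (requires `sp_cmd`).
#' @param sp_cmd Command template for [external_sp_adapter()] when
#'   `sp_filter = "external"`.
#' @param hq_threshold Internal-Score threshold (percent) for the
#'   high-quality subset (default 2).
#' @param sp_trim Signal-peptide allowance used by [internal_score()]
#'   (default 25).
#' @param score_filtered Keep and score sequences that fail the
#'   signal-peptide filter instead of excluding them (their `sp_call` is
#'   still recorded; default `FALSE`).
#' @return An object of class `npp_run`: a list with `records` (ranked
#'   prediction tibble), `removed` (invalid records and reasons),
#'   `summary` (one-row partition tibble), `agreement` (histogram tibble)
#'   and the run parameters. `tidy()` returns the records, `glance()` the
#'   summary.
#' @export
npp_run <- function(sequences, bundle,
                    sp_filter = c("off", "heuristic", "external"),
                    sp_cmd = NULL, hq_threshold = 2, sp_trim = 25,
                    score_filtered = FALSE) {
  sp_filter <- match.arg(sp_filter)
  stopifnot(inherits(bundle, "nppred_bundle"))
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- read_fasta(sequences)
  }
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  sequences <- dplyr::mutate(sequences, id = as.character(.data$id),
                             length = nchar(.data$residues),
                             .input_order = dplyr::row_number())

  checked <- validate_sequences(sequences)
  removed <- checked |>
    dplyr::filter(!.data$valid) |>
    dplyr::select("id", "reason")
  kept <- dplyr::filter(checked, .data$valid)

  # signal-peptide filter
  if (nrow(kept) > 0) {
    sp_call <- switch(sp_filter,
      off = rep(NA, nrow(kept)),
      heuristic = sp_heuristic(kept),
      external = {
        if (is.null(sp_cmd)) {
          stop("sp_filter = \"external\" requires `sp_cmd`", call. = FALSE)
        }
        unname(external_sp_adapter(sp_cmd, kept))
      }
    )
    kept$sp_call <- sp_call
  } else {
    kept$sp_call <- logical(0)
  }
  if (sp_filter != "off" && !score_filtered) {
    sp_excluded <- dplyr::filter(kept, !.data$sp_call)
    kept <- dplyr::filter(kept, .data$sp_call)
  } else {
    sp_excluded <- kept[0, ]
  }

  if (nrow(kept) > 0) {
    features <- extract_features(kept)
    records <- predict(bundle, features) |>
      call_positive(thresholds = bundle$thresholds) |>
      dplyr::mutate(
        internal_score = internal_score(kept, sp_trim = sp_trim),
        below_sp_length = kept$length <= sp_trim,
        sp_call = kept$sp_call,
        .input_order = kept$.input_order,
        max_prob = pmax(.data$prob_random_forest,
                        .data$prob_gradient_boosting,
                        .data$prob_linear_svm, .data$prob_minimal_tree),
        high_quality = .data$overall_call &
          .data$internal_score >= hq_threshold
      ) |>
      dplyr::arrange(dplyr::desc(.data$internal_score),
                     dplyr::desc(.data$max_prob), .data$.input_order) |>
      dplyr::select(-".input_order", -"max_prob")
  } else {
    records <- tibble::tibble(
      id = character(), prob_random_forest = numeric(),
      prob_gradient_boosting = numeric(), prob_linear_svm = numeric(),
      prob_minimal_tree = numeric(), call_random_forest = logical(),
      call_gradient_boosting = logical(), call_linear_svm = logical(),
      call_minimal_tree = logical(), overall_call = logical(),
      n_models_agreeing = integer(), internal_score = numeric(),
      below_sp_length = logical(), sp_call = logical(),
      high_quality = logical()
    )
  }

  summary <- tibble::tibble(
    n_input = nrow(sequences),
    n_removed_invalid = nrow(removed),
    n_sp_filtered = nrow(sp_excluded),
    n_scored = nrow(records),
    n_positive = sum(records$overall_call),
    n_negative = sum(!records$overall_call),
    n_high_quality = sum(records$high_quality),
    hq_threshold = hq_threshold,
    sp_filter = sp_filter
  )

  structure(
    list(records = records, removed = removed, summary = summary,
         agreement = agreement_partition(records),
         hq_threshold = hq_threshold, sp_filter = sp_filter,
         sp_trim = sp_trim),
    class = "npp_run"
  )
}

#' @export
print.npp_run <- function(x, ...) {
  s <- x$summary
  cat("<npp_run>", s$n_input, "input sequences:",
      s$n_removed_invalid, "removed (invalid residues),",
      s$n_sp_filtered, "filtered (no signal peptide),",
      s$n_positive, "positive /", s$n_negative, "negative\n")
  cat("  high-quality (IS >=", x$hq_threshold, "%):", s$n_high_quality,
      "\n")
  invisible(x)
}

#' Ranked prediction records of a run
#' @param x An `npp_run`.
#' @param ... Unused.
#' @return The ranked records tibble.
#' @export
tidy.npp_run <- function(x, ...) {
  x$records
}

#' One-row summary of a run
#' @param x An `npp_run`.
#' @param ... Unused.
#' @return The one-row partition tibble.
#' @export
glance.npp_run <- function(x, ...) {
  x$summary
}

#' High-quality subset of a run
#'
#' Positive calls whose Internal Score meets the run's threshold.
#'
#' @param run An `npp_run`.
#' @return Tibble of high-quality records (ranking preserved).
#' @export
high_quality <- function(run) {
  dplyr::filter(run$records, .data$high_quality)
}

#' Write all output tables of a run
#'
#' Writes `summary.tsv`, `detailed.tsv` (all scored records),
#' `high_quality.tsv`, `removed.tsv` and `positive.fasta` (positive
#' predictions, for forwarding to downstream cleavage-site tools) into a
#' directory.
#'
#' @param run An `npp_run`.
#' @param dir Output directory (created if needed).
#' @param sequences The input sequences (tibble with `id`, `residues`);
#'   needed to emit `positive.fasta`. Optional.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, sequences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$summary, file.path(dir, "summary.tsv"))
  write_results(run$records, file.path(dir, "detailed.tsv"))
  write_results(high_quality(run), file.path(dir, "high_quality.tsv"))
  readr::write_tsv(run$removed, file.path(dir, "removed.tsv"))
  if (!is.null(sequences)) {
    pos_ids <- run$records$id[run$records$overall_call]
    pos <- dplyr::filter(sequences, .data$id %in% pos_ids)
    if (nrow(pos) > 0) {
      write_fasta(pos, file.path(dir, "positive.fasta"))
    }
  }
  invisible(dir)
}
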