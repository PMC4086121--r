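# Feature extraction: every sequence maps to a fixed, ordered vector of
# 560 descriptors in three groups:
#   composition (20) | bigram (400) | physicochemical/statistical (140)
# The name order is frozen by feature_catalog(); trained models store the
# catalog version and refuse vectors built under a different one.

#' Amino-acid composition
#'
#' @param residues A validated residue string.
#' @return Named numeric vector of 20 frequencies (count / length) in fixed
#'   alphabetical order, names prefixed `comp_`.
#' @export
aa_composition <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  counts <- tabulate(match(chars, AA_ALPHABET), nbins = 20L)
  stats::setNames(counts / length(chars), paste0("comp_", AA_ALPHABET))
}

#' Bigram (dipeptide) frequencies
#'
#' Overlapping ordered residue pairs, normalized by the number of adjacent
#' pairs (L - 1) so the group sums to one independently of sequence length.
#' Sequences of length 1 return all zeros.
#'
#' @param residues A validated residue string.
#' @return Named numeric vector of 400 frequencies in lexicographic pair
#'   order, names prefixed `bg_`.
#' @export
bigram_frequencies <- function(residues) {
  nm <- paste0("bg_", rep(AA_ALPHABET, each = 20L), AA_ALPHABET)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 2L) {
    return(stats::setNames(numeric(400L), nm))
  }
  idx <- match(chars, AA_ALPHABET)
  pair <- (idx[-L] - 1L) * 20L + idx[-1L]
  stats::setNames(tabulate(pair, nbins = 400L) / (L - 1L), nm)
}

# Net charge of a residue-count vector at a given pH
# (Henderson-Hasselbalch over the EMBOSS pKa set, including termini).
charge_at_ph <- function(counts, ph) {
  n_pos <- c(Nterm = 1, K = counts[["K"]], R = counts[["R"]], H = counts[["H"]])
  n_neg <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]],
             C = counts[["C"]], Y = counts[["Y"]])
  pos <- sum(n_pos / (1 + 10^(ph - PKA_POSITIVE[names(n_pos)])))
  neg <- sum(n_neg / (1 + 10^(PKA_NEGATIVE[names(n_neg)] - ph)))
  pos - neg
}

# Isoelectric point by bisection on the net-charge curve.
isoelectric_point <- function(counts) {
  f <- function(ph) charge_at_ph(counts, ph)
  if (f(0) <= 0) return(0)
  if (f(14) >= 0) return(14)
  stats::uniroot(f, c(0, 14), tol = 1e-6)$root
}

# Longest run of residues drawn from `set` (0 if none).
max_run_in_set <- function(chars, set) {
  r <- rle(chars %in% set)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

# Lagged Pearson autocorrelation of a per-residue profile; 0 when undefined.
lag_autocorr <- function(x, lag) {
  n <- length(x)
  if (n <= lag + 2L) return(0)
  a <- x[seq_len(n - lag)]
  b <- x[seq_len(n - lag) + lag]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# Centered moving average of the Kyte-Doolittle profile (window 9); whole
# sequences shorter than the window collapse to a single mean value.
hydropathy_profile <- function(chars, window = 9L) {
  kd <- unname(KD_HYDROPATHY[chars])
  L <- length(kd)
  if (L < window) return(mean(kd))
  cs <- cumsum(c(0, kd))
  (cs[(window + 1):(L + 1)] - cs[1:(L - window + 1)]) / window
}

# The 140 physicochemical / statistical descriptors for one sequence.
# See ?physchem_features for the catalog documentation.
physchem_one <- function(residues, sp_trim = 25L) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  counts <- stats::setNames(tabulate(match(chars, AA_ALPHABET), 20L), AA_ALPHABET)
  comp <- counts / L
  kd_raw <- unname(KD_HYDROPATHY[chars])
  eff_len <- max(L - sp_trim, 1L)

  m <- find_basic_sites(residues)
  frac_of <- function(set) sum(comp[set])

  core <- c(
    pc_length = L,
    pc_mol_weight = sum(counts * AA_WEIGHT) - (L - 1) * WATER_MASS,
    pc_isoelectric_point = isoelectric_point(counts),
    pc_gravy = mean(kd_raw),
    pc_instability_index =
      if (L < 2) 0 else 10 / (L - 1) * sum(DIWV[cbind(chars[-L], chars[-1])]),
    pc_aromaticity = frac_of(c("F", "W", "Y")),
    pc_net_charge_ph7 = charge_at_ph(counts, 7)
  )

  fractions <- c(
    pc_frac_charged = frac_of(AA_CLASSES$charged),
    pc_frac_polar = frac_of(AA_CLASSES$polar),
    pc_frac_hydrophobic = frac_of(AA_CLASSES$hydrophobic),
    pc_frac_aromatic = frac_of(AA_CLASSES$aromatic),
    pc_frac_tiny = frac_of(AA_CLASSES$tiny),
    pc_frac_basic = frac_of(AA_CLASSES$basic),
    pc_frac_acidic = frac_of(AA_CLASSES$acidic),
    pc_frac_aliphatic = frac_of(AA_CLASSES$aliphatic)
  )

  n_single_trim <- sum(m$single_basic > sp_trim)
  basic_counts <- c(
    pc_count_K = counts[["K"]],
    pc_count_R = counts[["R"]],
    pc_count_single_basic = m$n_single,
    pc_count_dibasic = m$n_dibasic,
    pc_count_tribasic = m$n_tribasic,
    pc_dens_K = 100 * counts[["K"]] / L,
    pc_dens_R = 100 * counts[["R"]] / L,
    pc_dens_single_basic = 100 * m$n_single / L,
    pc_dens_dibasic = 100 * m$n_dibasic / L,
    pc_dens_tribasic = 100 * m$n_tribasic / L,
    pc_dens_K_trim = 100 * counts[["K"]] / eff_len,
    pc_dens_R_trim = 100 * counts[["R"]] / eff_len,
    pc_dens_single_basic_trim = 100 * m$n_single / eff_len,
    pc_dens_dibasic_trim = 100 * m$n_dibasic / eff_len,
    pc_dens_tribasic_trim = 100 * m$n_tribasic / eff_len
  )

  nterm <- chars[seq_len(min(25L, L))]
  cterm <- chars[seq.int(max(1L, L - 24L), L)]
  nt_counts <- tabulate(match(nterm, AA_ALPHABET), 20L)
  ct_counts <- tabulate(match(cterm, AA_ALPHABET), 20L)
  windows <- c(
    stats::setNames(nt_counts / length(nterm), paste0("pc_nterm25_", AA_ALPHABET)),
    stats::setNames(ct_counts / length(cterm), paste0("pc_cterm25_", AA_ALPHABET))
  )

  p_nz <- comp[comp > 0]
  hprof <- hydropathy_profile(chars)
  profile_stats <- c(
    pc_entropy_composition = -sum(p_nz * log2(p_nz)),
    pc_max_run_basic = max_run_in_set(chars, BASIC_RESIDUES),
    pc_max_run_hydrophobic = max_run_in_set(chars, AA_CLASSES$hydrophobic),
    pc_hydro_mean = mean(hprof),
    pc_hydro_var = if (length(hprof) > 1) stats::var(hprof) else 0,
    pc_hydro_min = min(hprof),
    pc_hydro_max = max(hprof),
    pc_hydro_q25 = unname(stats::quantile(hprof, 0.25)),
    pc_hydro_q75 = unname(stats::quantile(hprof, 0.75))
  )

  # signal-peptide-oriented terminal summaries
  nt_kd <- unname(KD_HYDROPATHY[nterm])
  sp_core <- if (length(nt_kd) >= 7L) {
    max(vapply(seq_len(length(nt_kd) - 6L),
               function(i) mean(nt_kd[i:(i + 6L)]), numeric(1)))
  } else {
    mean(nt_kd)
  }
  terminal <- c(
    pc_nterm25_gravy = mean(nt_kd),
    pc_nterm25_net_charge =
      sum(nterm %in% BASIC_RESIDUES) - sum(nterm %in% AA_CLASSES$acidic),
    pc_nterm25_frac_hydrophobic = mean(nterm %in% AA_CLASSES$hydrophobic),
    pc_cterm25_gravy = mean(unname(KD_HYDROPATHY[cterm])),
    pc_cterm25_net_charge =
      sum(cterm %in% BASIC_RESIDUES) - sum(cterm %in% AA_CLASSES$acidic),
    pc_sp_core_score = sp_core
  )

  structure_prop <- c(
    pc_frac_helix = frac_of(AA_CLASSES$helix),
    pc_frac_sheet = frac_of(AA_CLASSES$sheet),
    pc_frac_turn = frac_of(AA_CLASSES$turn)
  )

  misc <- c(
    pc_flexibility_mean = sum(comp * FLEXIBILITY[AA_ALPHABET]),
    pc_aliphatic_index = 100 * (comp[["A"]] + 2.9 * comp[["V"]] +
                                  3.9 * (comp[["I"]] + comp[["L"]])),
    pc_mean_residue_weight = sum(comp * AA_WEIGHT[AA_ALPHABET]),
    pc_charge_ph5 = charge_at_ph(counts, 5),
    pc_charge_ph9 = charge_at_ph(counts, 9)
  )

  run_starts <- c(m$single_basic, m$dibasic, m$tribasic)
  run_starts <- sort(run_starts)
  gaps <- if (length(run_starts) >= 2L) diff(run_starts) else numeric(0)
  spacing <- c(
    pc_basic_spacing_mean = if (length(gaps)) mean(gaps) else 0,
    pc_basic_spacing_sd = if (length(gaps) >= 2L) stats::sd(gaps) else 0,
    pc_basic_spacing_min = if (length(gaps)) min(gaps) else 0,
    pc_basic_spacing_max = if (length(gaps)) max(gaps) else 0,
    pc_n_basic_runs = length(run_starts),
    pc_max_nonbasic_gap = max_run_in_set(chars, setdiff(AA_ALPHABET, BASIC_RESIDUES))
  )

  quarter <- ceiling(seq_len(L) * 4L / L)
  q_frac <- function(set) {
    vapply(1:4, function(q) {
      idx <- quarter == q
      if (!any(idx)) 0 else mean(chars[idx] %in% set)
    }, numeric(1))
  }
  quarters <- c(
    stats::setNames(q_frac(BASIC_RESIDUES), paste0("pc_q", 1:4, "_frac_basic")),
    stats::setNames(q_frac(AA_CLASSES$hydrophobic),
                    paste0("pc_q", 1:4, "_frac_hydrophobic"))
  )

  charge_prof <- (chars %in% BASIC_RESIDUES) - (chars %in% AA_CLASSES$acidic)
  autocorr <- c(
    stats::setNames(vapply(1:10, function(l) lag_autocorr(kd_raw, l), numeric(1)),
                    paste0("pc_hydro_autocorr_", 1:10)),
    stats::setNames(vapply(1:10, function(l) lag_autocorr(charge_prof, l), numeric(1)),
                    paste0("pc_charge_autocorr_", 1:10))
  )

  count_pair <- function(p) {
    if (L < 2L) return(0L)
    sum(chars[-L] == substr(p, 1, 1) & chars[-1] == substr(p, 2, 2))
  }
  pairs <- c(
    pc_count_KK = count_pair("KK"), pc_count_KR = count_pair("KR"),
    pc_count_RK = count_pair("RK"), pc_count_RR = count_pair("RR")
  )

  bg <- bigram_frequencies(residues)
  bg_nz <- bg[bg > 0]
  remainder <- c(
    pc_entropy_bigram = if (length(bg_nz)) -sum(bg_nz * log2(bg_nz)) else 0,
    pc_net_charge_per100 = 100 * charge_at_ph(counts, 7) / L,
    pc_log_length = log(L),
    pc_count_C = counts[["C"]],
    pc_frac_GP = comp[["G"]] + comp[["P"]],
    pc_comp_chisq = sum((counts - L / 20)^2 / (L / 20)),
    pc_extinction_per_residue =
      (EXTINCTION[["W"]] * counts[["W"]] + EXTINCTION[["Y"]] * counts[["Y"]] +
         EXTINCTION[["C"]] * counts[["C"]]) / L,
    pc_frac_small = frac_of(AA_CLASSES$small),
    pc_count_basic_total = counts[["K"]] + counts[["R"]]
  )

  c(core, fractions, basic_counts, windows, profile_stats, terminal,
    structure_prop, misc, spacing, quarters, autocorr, pairs, remainder)
}

#' Physicochemical and statistical descriptors
#'
#' Computes the 140-descriptor group of the feature vector: global indices
#' (length, molecular weight, isoelectric point, GRAVY hydropathy,
#' instability index, aromaticity, net charge), residue-class fractions,
#' counts and per-100-residue densities of basic residues and of
#' single/dibasic/tribasic motifs (full-length and after trimming a 25-aa
#' signal-peptide allowance), N- and C-terminal 25-residue window
#' compositions, composition and bigram entropies, maximal basic and
#' hydrophobic run lengths, windowed hydropathy-profile statistics,
#' terminal hydropathy/charge summaries, secondary-structure propensity
#' fractions, basic-site spacing statistics, per-quarter basic and
#' hydrophobic fractions, and lagged autocorrelations of the hydropathy
#' and charge profiles. Sequences shorter than a window are summarised
#' over the residues available.
#'
#' The exact names and order are fixed by the catalog version
#' (`feature_catalog()`).
#'
#' @param residues A validated residue string.
#' @return Named numeric vector of exactly 140 descriptors, names prefixed
#'   `pc_`.
#' @export
physchem_features <- function(residues) {
  physchem_one(residues)
}

#' The frozen feature catalog
#'
#' @return A tibble with columns `name` and `group`
#'   (`composition`/`bigram`/`physchem`), 560 rows, in the fixed extraction
#'   order, with the catalog version as attribute `catalog_version`.
#' @export
feature_catalog <- function() {
  nm <- c(names(aa_composition("A")),
          names(bigram_frequencies("AA")),
          names(physchem_one("ACDEFGHIKLMNPQRSTVWY")))
  out <- tibble::tibble(
    name = nm,
    group = rep(c("composition", "bigram", "physchem"), c(20L, 400L, 140L))
  )
  attr(out, "catalog_version") <- FEATURE_CATALOG_VERSION
  out
}

#' Extract the full 560-dimensional feature matrix
#'
#' Converts validated sequences into the fixed descriptor vector:
#' 20 composition + 400 bigram + 140 physicochemical features, one row per
#' sequence. Extraction is deterministic; the result carries the catalog
#' version so trained models can verify compatibility.
#'
#' @param sequences A tibble with columns `id` and `residues` (validated),
#'   or a character vector of residue strings.
#' @return A tibble with column `id` followed by 560 feature columns, and
#'   attribute `catalog_version`.
#' @export
#' @examples
#' extract_features(tibble::tibble(id = "q", residues = "MKKRLLAVAASSTTDE"))
extract_features <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- tibble::tibble(id = as.character(seq_along(sequences)),
                                residues = sequences)
  }
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  bad <- validate_sequences(sequences)
  if (any(!bad$valid)) {
    stop("invalid sequences passed to extract_features(); validate first (",
         sum(!bad$valid), " offending record(s))", call. = FALSE)
  }
  rows <- purrr::map(sequences$residues, function(s) {
    c(aa_composition(s), bigram_frequencies(s), physchem_one(s))
  })
  mat <- do.call(rbind, rows)
  stopifnot(ncol(mat) == 560L)
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(sequences$id)), out)
  attr(out, "catalog_version") <- FEATURE_CATALOG_VERSION
  out
}

# Internal: strip the id column and return the numeric matrix in catalog
# order; errors if columns are missing or misordered relative to `names`.
feature_matrix <- function(features, names = NULL) {
  stopifnot("id" %in% colnames(features))
  mat <- as.matrix(features[, setdiff(colnames(features), "id")])
  if (!is.null(names)) {
    if (!all(names %in% colnames(mat))) {
      stop("feature table is missing ",
           sum(!(names %in% colnames(mat))), " expected feature(s)",
           call. = FALSE)
    }
    mat <- mat[, names, drop = FALSE]
  }
  storage.mode(mat) <- "double"
  mat
}

#' Export a feature matrix to TSV
#'
#' Header row of feature names, one row per sequence, first column `id`.
#'
#' @param features A feature tibble from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_tsv(features, path)
  invisible(path)
}
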