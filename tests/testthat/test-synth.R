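test_that("generation is deterministic: same config + seed, identical FASTA bytes", {
  cfg <- synth_config(n_sequences = 15, seed = 8)
  p1 <- generate_positive(cfg)
  p2 <- generate_positive(cfg)
  expect_identical(p1$sequences$residues, p2$sequences$residues)
  expect_identical(p1$ground_truth, p2$ground_truth)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p1$sequences, f1); write_fasta(p2$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  n1 <- generate_negative(cfg)
  n2 <- generate_negative(cfg)
  expect_identical(n1$residues, n2$residues)
})

test_that("every generated sequence passes validation", {
  for (cls in c("uniform", "nuclear", "globular")) {
    cfg <- synth_config(n_sequences = 20, seed = 4, negative_class = cls)
    expect_true(all(validate_sequences(generate_negative(cfg))$valid))
  }
  cfg <- synth_config(n_sequences = 20, seed = 4)
  expect_true(all(validate_sequences(generate_positive(cfg)$sequences)$valid))
})

test_that("planted flanks are a subset of scanned motifs, with matching class", {
  cfg <- synth_config(n_sequences = 25, seed = 12)
  p <- generate_positive(cfg)
  found <- motif_table(p$sequences)
  truth <- p$ground_truth
  joined <- dplyr::left_join(truth, found,
                             by = c("id", "start", "motif_class"))
  # every planted motif is found at its planted start with its class
  expect_false(anyNA(joined$end.y))
  # dibasic flanks span exactly two residues as emitted
  di <- dplyr::filter(joined, .data$motif_class == "dibasic")
  expect_true(all(di$end.y - di$start + 1 == 2))
})

test_that("precursor architecture produces the expected motif load", {
  # seven dibasic-flanked repeats: at least 7 planted motifs and IS well
  # above a sparse background
  cfg <- synth_config(n_sequences = 10, seed = 99,
                      n_repeats_range = c(7L, 7L),
                      flank_weights = c(KK = 1, KR = 0, RK = 0, RR = 0,
                                        tribasic = 0))
  p <- generate_positive(cfg)
  counts <- vapply(p$sequences$residues,
                   function(s) find_basic_sites(s)$n_dibasic, integer(1))
  expect_true(all(counts >= 7))
  expect_true(all(internal_score(p$sequences) > 1.8))
  # zero repeats: no planted flanks, empty ground truth
  cfg0 <- synth_config(n_sequences = 5, seed = 2,
                       n_repeats_range = c(0L, 0L))
  p0 <- generate_positive(cfg0)
  expect_equal(nrow(p0$ground_truth), 0)
})

test_that("negative classes have lower clustered-basic density than positives", {
  pos <- generate_positive(synth_config(n_sequences = 40, seed = 71))
  pos_is <- mean(internal_score(pos$sequences))
  for (cls in c("uniform", "nuclear", "globular")) {
    neg <- generate_negative(synth_config(n_sequences = 40, seed = 72,
                                          negative_class = cls))
    expect_lt(mean(internal_score(neg)), pos_is)
  }
  # nuclear-like negatives carry no basic runs of length >= 2 at all
  neg <- generate_negative(synth_config(n_sequences = 20, seed = 73,
                                        negative_class = "nuclear"))
  runs <- vapply(neg$residues, function(s) {
    m <- find_basic_sites(s); m$n_dibasic + m$n_tribasic
  }, integer(1))
  expect_true(all(runs == 0))
  # but they are K/R-enriched overall relative to background
  kr_frac <- mean(vapply(neg$residues, function(s) {
    mean(strsplit(s, "")[[1]] %in% c("K", "R"))
  }, numeric(1)))
  expect_gt(kr_frac, 0.09)
})

test_that("sampled composition converges to the configured background", {
  flat <- stats::setNames(rep(1 / 20, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  cfg <- synth_config(n_sequences = 250, seed = 5,
                      length_range = c(400L, 400L), background = flat)
  neg <- generate_negative(cfg)  # 1e5 residues
  chars <- strsplit(paste(neg$residues, collapse = ""), "")[[1]]
  comp <- table(chars) / length(chars)
  expect_true(all(abs(comp - 0.05) < 0.005))
})

test_that("synthetic sets export FASTA plus ground-truth TSV", {
  dir <- withr::local_tempdir()
  p <- generate_positive(synth_config(n_sequences = 3, seed = 1))
  write_synth(p, dir, prefix = "pos")
  expect_true(file.exists(file.path(dir, "pos.fasta")))
  gt <- readr::read_tsv(file.path(dir, "pos_ground_truth.tsv"),
                        show_col_types = FALSE)
  expect_named(gt, c("id", "start", "end", "motif_class"))
})

test_that("config validation rejects inconsistent ranges", {
  expect_error(synth_config(n_repeats_range = c(5L, 2L)))
  expect_error(synth_config(background = c(A = 1)))
  expect_error(synth_config(background = stats::setNames(
    rep(0.06, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])),
    "sum to 1")
})
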