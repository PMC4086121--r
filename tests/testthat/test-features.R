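test_that("feature vector is exactly 560 = 20 + 400 + 140, stable order", {
  fc <- feature_catalog()
  expect_equal(nrow(fc), 560L)
  expect_equal(as.vector(table(fc$group)[c("composition", "bigram", "physchem")]),
               c(20L, 400L, 140L))
  f <- extract_features("MKKRLLAVAASSTTDE")
  expect_equal(setdiff(names(f), "id"), fc$name)
  # deterministic: identical vectors for the same sequence
  f2 <- extract_features("MKKRLLAVAASSTTDE")
  expect_identical(f, f2)
})

test_that("composition matches direct counts", {
  expect_equal(unname(aa_composition("AAAA")["comp_A"]), 1)
  expect_equal(sum(aa_composition("AAAA")), 1)
  cc <- aa_composition("ACDE")
  expect_equal(unname(cc[c("comp_A", "comp_C", "comp_D", "comp_E")]),
               rep(0.25, 4))
  cc <- aa_composition("MKKR")
  expect_equal(unname(cc[c("comp_K", "comp_M", "comp_R")]),
               c(0.5, 0.25, 0.25))
})

test_that("bigram frequencies match the overlapping-pair definition", {
  bg <- bigram_frequencies("ACAC")
  expect_equal(unname(bg["bg_AC"]), 2 / 3)
  expect_equal(unname(bg["bg_CA"]), 1 / 3)
  expect_equal(sum(bg), 1)
  expect_equal(unname(bigram_frequencies("AAAA")["bg_AA"]), 1)
  expect_equal(sum(bigram_frequencies("A")), 0)
})

test_that("composition and bigram groups sum to one on random sequences, and bigrams match a nested-loop oracle", {
  withr::local_seed(11)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    s <- random_sequence(sample(2:300, 1))
    expect_equal(sum(aa_composition(s)), 1, tolerance = 1e-9)
    bg <- bigram_frequencies(s)
    expect_equal(sum(bg), 1, tolerance = 1e-9)
    # oracle: count every ordered pair with an explicit double loop
    chars <- strsplit(s, "")[[1]]
    for (probe in sample(names(bg)[bg > 0], min(3, sum(bg > 0)))) {
      a <- substr(probe, 4, 4); b <- substr(probe, 5, 5)
      count <- 0L
      for (i in seq_len(length(chars) - 1)) {
        if (chars[i] == a && chars[i + 1] == b) count <- count + 1L
      }
      expect_equal(unname(bg[probe]), count / (length(chars) - 1))
    }
  }
})

test_that("permuting residues preserves composition but changes bigrams", {
  withr::local_seed(3)
  s <- random_sequence(120)
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(aa_composition(s), aa_composition(shuffled))
  expect_false(isTRUE(all.equal(bigram_frequencies(s),
                                bigram_frequencies(shuffled))))
})

test_that("physchem descriptors match hand-computed values", {
  pc <- physchem_features(strrep("A", 100))
  expect_equal(unname(pc["pc_gravy"]), 1.8)  # Kyte-Doolittle Ala
  expect_equal(unname(pc["pc_length"]), 100)
  expect_equal(unname(pc["pc_frac_hydrophobic"]), 1)
  expect_equal(unname(pc["pc_entropy_composition"]), 0)
  # length feature is the residue count on arbitrary sequences
  withr::local_seed(5)
  for (L in c(1, 7, 30)) {
    s <- random_sequence(L)
    expect_equal(unname(physchem_features(s)["pc_length"]), L)
  }
})

test_that("KKKK maximizes basic fraction and overlapping-basic-pair counts over length-4 sequences", {
  pc <- physchem_features("KKKK")
  expect_equal(unname(pc["pc_frac_basic"]), 1)
  # brute force over all length-4 sequences on {A,K,R}: no sequence has
  # more adjacent basic-basic pairs than a pure basic run
  pair_count <- function(s) {
    sum(pc_of <- {
      chars <- strsplit(s, "")[[1]]
      chars[-4] %in% c("K", "R") & chars[-1] %in% c("K", "R")
    })
  }
  grid <- expand.grid(a = c("A", "K", "R"), b = c("A", "K", "R"),
                      c = c("A", "K", "R"), d = c("A", "K", "R"))
  all_counts <- apply(grid, 1, function(r) pair_count(paste(r, collapse = "")))
  kkkk_pairs <- sum(pc[c("pc_count_KK", "pc_count_KR",
                         "pc_count_RK", "pc_count_RR")])
  expect_equal(kkkk_pairs, max(all_counts))
  # and a full basic run of length 4 is one tribasic motif, not dibasics
  expect_equal(unname(pc["pc_count_tribasic"]), 1)
  expect_equal(unname(pc["pc_count_dibasic"]), 0)
})

test_that("short sequences fall back to truncated windows without error", {
  pc <- physchem_features("MK")
  expect_equal(unname(pc["pc_length"]), 2)
  expect_equal(sum(pc[paste0("pc_nterm25_", c("M", "K"))]), 1)
  pc1 <- physchem_features("W")
  expect_equal(unname(pc1["pc_instability_index"]), 0)
  expect_false(anyNA(pc1))
})

test_that("feature names serialize stably through the TSV export", {
  f <- extract_features(c("MKKRLLAVAA", "ACDEFGHIKL"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(f, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), names(f))
  expect_equal(back$pc_length, f$pc_length)
})

test_that("feature extraction refuses invalid sequences", {
  expect_error(extract_features(c("MKXR")), "invalid")
})
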