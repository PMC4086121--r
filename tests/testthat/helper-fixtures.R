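# Shared fixtures. Heavy objects (a trained bundle) are built once per
# test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Small but separable training set + trained bundle reused across tests.
get_test_set <- function() {
  if (is.null(.fixture_cache$set)) {
    .fixture_cache$set <- synth_training_set(n = 40, seed = 42)
  }
  .fixture_cache$set
}

get_test_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    ts <- get_test_set()
    .fixture_cache$bundle <- npp_train(ts$pos_features, ts$neg_features,
                                       seed = 42, folds = 6)
  }
  .fixture_cache$bundle
}

# Independent brute-force maximal-run scanner: walks the characters one
# by one, no rle(), no regex. Returns run starts by class.
brute_force_scan <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  single <- integer(0); dibasic <- integer(0); tribasic <- integer(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] %in% c("K", "R")) {
      start <- i
      len <- 0L
      while (i <= n && chars[i] %in% c("K", "R")) {
        len <- len + 1L
        i <- i + 1L
      }
      if (len == 1L) single <- c(single, start)
      else if (len == 2L) dibasic <- c(dibasic, start)
      else tribasic <- c(tribasic, start)
    } else {
      i <- i + 1L
    }
  }
  list(single = single, dibasic = dibasic, tribasic = tribasic)
}

# Random valid residue string.
random_sequence <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Write a small FASTA file and return its path.
write_tmp_fasta <- function(ids, residues, descriptions = NULL) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  headers <- if (is.null(descriptions)) ids else paste(ids, descriptions)
  writeLines(as.vector(rbind(paste0(">", headers), residues)), path)
  path
}
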