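test_that("confusion metrics match the printed formulas on worked examples", {
  cm <- confusion_metrics(tp = 9, tn = 8, fp = 1, fn = 2)
  expect_equal(cm$accuracy, 0.85)
  expect_equal(cm$precision, 0.9)
  expect_equal(cm$recall, 9 / 11)
  expect_equal(cm$mcc, 70 / sqrt(9900))
  perfect <- confusion_metrics(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "mcc")]),
               c(accuracy = 1, precision = 1, recall = 1, mcc = 1))
})

test_that("confusion metrics agree with an independent vector-based oracle on the exhaustive [0,10] grid", {
  grid <- expand.grid(tp = 0:10, tn = 0:10, fp = 0:10, fn = 0:10)
  grid <- grid[rowSums(grid) > 0, ]
  cm <- confusion_metrics(grid$tp, grid$tn, grid$fp, grid$fn)
  # oracle: materialize truth/prediction vectors; accuracy via mean of
  # agreement, MCC as the Pearson phi coefficient of the two vectors
  oracle <- function(tp, tn, fp, fn) {
    truth <- rep(c(1, 0, 0, 1), c(tp, tn, fp, fn))
    pred  <- rep(c(1, 0, 1, 0), c(tp, tn, fp, fn))
    phi <- suppressWarnings(stats::cor(truth, pred))
    c(acc = mean(truth == pred),
      prec = if (sum(pred) == 0) 0 else mean(truth[pred == 1]),
      rec = if (sum(truth) == 0) 0 else mean(pred[truth == 1]),
      mcc = if (is.na(phi)) 0 else phi)
  }
  idx <- seq_len(nrow(grid))
  o <- vapply(idx, function(i) oracle(grid$tp[i], grid$tn[i],
                                      grid$fp[i], grid$fn[i]),
              numeric(4))
  expect_equal(cm$accuracy, unname(o["acc", ]), tolerance = 1e-12)
  expect_equal(cm$precision, unname(o["prec", ]), tolerance = 1e-12)
  expect_equal(cm$recall, unname(o["rec", ]), tolerance = 1e-12)
  expect_equal(cm$mcc, unname(o["mcc", ]), tolerance = 1e-10)
  expect_true(all(cm$mcc >= -1 & cm$mcc <= 1))
  expect_true(all(cm$precision_undefined == (grid$tp + grid$fp == 0)))
})

test_that("AUC equals the pairwise Mann-Whitney brute force", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  brute <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    mean(cmp)
  }
  withr::local_seed(17)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force ties
    expect_equal(auc_score(scores, labels), brute(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), "one positive and one negative")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(23)
  for (i in 1:10) {
    labels <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- stats::rnorm(40) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("threshold calls use strict inequality and OR aggregation", {
  # 0.85 on a 0.8-threshold model is positive via that model alone
  one <- call_positive(c(0.85, 0.10, 0.10, 0.10))
  expect_true(one$call_random_forest)
  expect_true(one$overall_call)
  expect_equal(one$n_models_agreeing, 1L)
  # gradient boosting at 0.98 stays below its 0.99 cutoff
  gb <- call_positive(c(0.10, 0.98, 0.10, 0.10))
  expect_false(gb$call_gradient_boosting)
  expect_false(gb$overall_call)
  # exactly at threshold is NOT a call (strict >)
  at <- call_positive(c(0.8, 0.99, 0.8, 0.8))
  expect_false(at$overall_call)
  expect_false(call_positive(c(0, 0, 0, 0))$overall_call)
})

test_that("training is deterministic and recovers the planted separation", {
  ts <- get_test_set()
  b1 <- get_test_bundle()
  b2 <- npp_train(ts$pos_features, ts$neg_features, seed = 42, folds = 6)
  expect_equal(tidy(b1), tidy(b2))
  expect_identical(b1$minimal_feature_names, b2$minimal_feature_names)
  # all four models separate the synthetic classes in cross-validation
  expect_true(all(tidy(b1)$auc >= 0.95))

  # fresh-seed test set: held-out probabilities rank the classes
  te <- synth_training_set(n = 30, seed = 977)
  probs <- predict(b1, dplyr::bind_rows(te$pos_features, te$neg_features))
  labels <- rep(c(1, 0), each = 30)
  for (col in paste0("prob_", c("random_forest", "gradient_boosting",
                                "linear_svm", "minimal_tree"))) {
    expect_gte(auc_score(probs[[col]], labels), 0.95)
  }
  # repeated prediction is identical
  expect_identical(probs,
                   predict(b1, dplyr::bind_rows(te$pos_features,
                                                te$neg_features)))
})

test_that("null data (identical class distributions) gives chance-level AUC", {
  # one pool, labels assigned at random: no model should beat chance
  pool <- generate_negative(synth_config(n_sequences = 120, seed = 301,
                                         length_range = c(80L, 160L)))
  feats <- extract_features(pool)
  # flexible models on a finite random split fluctuate around chance, so
  # average the CV AUC over repeated random label assignments
  auc <- purrr::map_dfr(c(302, 500, 901), function(s) {
    idx <- withr::with_seed(s, sample(nrow(feats), 60))
    tidy(npp_train(feats[idx, ], feats[-idx, ], seed = 9, folds = 6))
  }) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(auc = mean(.data$auc))
  expect_true(all(auc$auc > 0.35 & auc$auc < 0.65))
})

test_that("minimal feature selection is deterministic, bounded, and finds motif-density signal", {
  ts <- get_test_set()
  s1 <- select_minimal_features(ts$pos_features, ts$neg_features, k = 20,
                                seed = 5)
  s2 <- select_minimal_features(ts$pos_features, ts$neg_features, k = 20,
                                seed = 5)
  expect_identical(s1, s2)
  expect_length(s1, 20)
  # the planted contrast is clustered-basic density: at least one
  # motif-density descriptor must rank in the subset
  motif_feats <- c("pc_count_dibasic", "pc_dens_dibasic",
                   "pc_dens_dibasic_trim", "pc_count_tribasic",
                   "pc_dens_tribasic", "pc_dens_tribasic_trim",
                   "pc_n_basic_runs", "pc_count_KK", "pc_count_KR",
                   "pc_count_RK", "pc_count_RR", "pc_max_run_basic")
  expect_gt(length(intersect(s1, motif_feats)), 0)
  expect_error(select_minimal_features(ts$pos_features, ts$neg_features,
                                       k = 600), "exceeds")
  # identity: k = catalog size returns the full catalog
  full <- select_minimal_features(ts$pos_features[1:10, ],
                                  ts$neg_features[1:10, ], k = 560, seed = 1)
  expect_setequal(full, setdiff(names(ts$pos_features), "id"))
})

test_that("minimal tree and full random forest give correlated calls", {
  b <- get_test_bundle()
  te <- synth_training_set(n = 100, seed = 31)
  probs <- predict(b, dplyr::bind_rows(te$pos_features, te$neg_features))
  expect_gt(stats::cor(probs$prob_random_forest, probs$prob_minimal_tree,
                       method = "spearman"), 0)
})

test_that("catalog-version mismatch is refused", {
  b <- get_test_bundle()
  f <- extract_features("MKKRLLAVAASSTTDE")
  attr(f, "catalog_version") <- "someone-elses-catalog-9.9"
  expect_error(predict(b, f), "catalog version mismatch")
})

test_that("training rejects degenerate inputs", {
  ts <- get_test_set()
  expect_error(npp_train(ts$pos_features[1:3, ], ts$neg_features[1:3, ],
                         folds = 6), "at least")
  expect_error(npp_train(ts$pos_features[0, ], ts$neg_features, folds = 6))
})

test_that("bundles survive a round-trip through disk", {
  b <- get_test_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$thresholds$gradient_boosting, 0.99)
  b2 <- read_bundle(dir)
  f <- extract_features(get_test_set()$pos[1:5, ])
  expect_equal(predict(b, f), predict(b2, f), tolerance = 1e-12)
})
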