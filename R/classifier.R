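# Four-model supervised ensemble over the 560-feature vector:
#   random_forest      probability forest (tree-ensemble slot)
#   gradient_boosting  boosted trees, logistic objective
#   linear_svm         linear SVM with Platt-calibrated probabilities
#   minimal_tree       probability forest restricted to the k most
#                      discriminative features
# A sequence is called positive by a model when its probability is
# strictly greater than that model's threshold; the overall call is the
# OR over the four models.

MODEL_NAMES <- c("random_forest", "gradient_boosting", "linear_svm",
                 "minimal_tree")

#' Default per-model probability thresholds
#'
#' Probabilities must exceed 0.8 for the random forest, linear SVM and
#' minimal-tree models and 0.99 for the gradient-boosting model before a
#' model calls a sequence positive (strict inequality).
#'
#' @return Named numeric vector of four thresholds.
#' @export
default_thresholds <- function() {
  c(random_forest = 0.8, gradient_boosting = 0.99,
    linear_svm = 0.8, minimal_tree = 0.8)
}

#' Binary-classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall and the Matthews correlation
#' coefficient from true/false positive/negative counts:
#' accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' MCC is defined as 0 when any denominator factor is 0. An undefined
#' precision (TP+FP = 0) is reported as 0 with `precision_undefined` set.
#'
#' @param tp,tn,fp,fn Non-negative counts (vectorized).
#' @return A tibble with the counts, the four metrics and the
#'   `precision_undefined` flag.
#' @export
#' @examples
#' confusion_metrics(tp = 9, tn = 8, fp = 1, fn = 2)
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(all(c(tp, tn, fp, fn) >= 0), all(tp + tn + fp + fn > 0))
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = ifelse(tp + fp == 0, 0, tp / (tp + fp)),
    precision_undefined = tp + fp == 0,
    recall = ifelse(tp + fn == 0, 0, tp / (tp + fn)),
    mcc = ifelse(denom == 0, 0, (tp * tn - fp * fn) / sqrt(denom))
  )
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half; computed from midranks.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (logical, or 0/1).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_score(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
auc_score <- function(scores, labels) {
  labels <- as.logical(as.integer(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("auc_score() needs at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# ---- model fitting internals ------------------------------------------

fit_random_forest <- function(x, y, seed, num_trees = 300L, feature_names = NULL) {
  if (!is.null(feature_names)) x <- x[, feature_names, drop = FALSE]
  df <- as.data.frame(x)
  fit <- ranger::ranger(
    x = df, y = y, probability = TRUE, num.trees = num_trees,
    seed = seed, num.threads = 1L
  )
  list(kind = "ranger", fit = fit, feature_names = feature_names)
}

fit_gradient_boosting <- function(x, y, seed, nrounds = 150L) {
  d <- xgboost::xgb.DMatrix(x, label = as.integer(y == "pos"))
  params <- list(objective = "binary:logistic", eta = 0.1, max_depth = 3L,
                 nthread = 1L, subsample = 1, colsample_bytree = 1)
  fit <- xgboost::xgb.train(params = params, data = d, nrounds = nrounds,
                            verbose = 0)
  list(kind = "xgboost", fit = fit)
}

# Linear SVM with sigmoid (Platt) calibration fitted on out-of-fold
# decision values of an inner 3-fold split, so the calibration curve is
# not learned from the same margins it rescales.
fit_linear_svm <- function(x, y, seed, cost = 1) {
  centers <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  sds[sds < 1e-8] <- 1
  xs <- scale(x, center = centers, scale = sds)
  inner <- withr::with_seed(seed + 7L, make_folds(y, 3L))
  dv_oof <- numeric(nrow(xs))
  for (f in 1:3) {
    tr <- inner != f
    m <- e1071::svm(x = xs[tr, , drop = FALSE], y = y[tr],
                    kernel = "linear", cost = cost, scale = FALSE)
    dv_oof[!tr] <- attr(predict(m, xs[!tr, , drop = FALSE],
                                decision.values = TRUE), "decision.values")[, 1]
  }
  # with widely separated classes the logistic fit is quasi-separable;
  # the clipped sigmoid is still the calibration we want
  platt <- suppressWarnings(
    stats::glm.fit(cbind(1, dv_oof), as.integer(y == "pos"),
                   family = stats::binomial())$coefficients
  )
  fit <- e1071::svm(x = xs, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  list(kind = "svm", fit = fit, platt = platt, centers = centers, sds = sds)
}

predict_one_model <- function(model, x) {
  switch(model$kind,
    ranger = {
      if (!is.null(model$feature_names)) {
        x <- x[, model$feature_names, drop = FALSE]
      }
      predict(model$fit, as.data.frame(x),
              num.threads = 1L)$predictions[, "pos"]
    },
    xgboost = {
      predict(model$fit, xgboost::xgb.DMatrix(x))
    },
    svm = {
      xs <- scale(x, center = model$centers, scale = model$sds)
      dv <- attr(predict(model$fit, xs, decision.values = TRUE),
                 "decision.values")[, 1]
      unname(stats::plogis(model$platt[1] + model$platt[2] * dv))
    },
    stop("unknown model kind: ", model$kind)
  )
}

# Stratified fold assignment (uses the current RNG state).
make_folds <- function(y, folds) {
  out <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    out[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  out
}

#' Rank features by discriminative importance
#'
#' Impurity importance of a probability forest fitted to the labeled
#' feature matrices, used to pick the subset scored by the minimal-tree
#' model.
#'
#' @param pos,neg Feature tibbles from [extract_features()] for the
#'   positive and negative training sets.
#' @param k Number of features to keep.
#' @param seed Integer seed.
#' @return Character vector of the `k` top-ranked feature names.
#' @export
select_minimal_features <- function(pos, neg, k = 20L, seed = 1L) {
  catalog <- setdiff(colnames(pos), "id")
  if (k > length(catalog)) {
    stop("k = ", k, " exceeds the catalog size (", length(catalog), ")",
         call. = FALSE)
  }
  x <- rbind(feature_matrix(pos, catalog), feature_matrix(neg, catalog))
  y <- factor(rep(c("pos", "neg"), c(nrow(pos), nrow(neg))),
              levels = c("neg", "pos"))
  rank_features(x, y, k, seed)
}

rank_features <- function(x, y, k, seed) {
  fit <- ranger::ranger(x = as.data.frame(x), y = y, probability = TRUE,
                        num.trees = 300L, importance = "impurity",
                        seed = seed, num.threads = 1L)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  names(imp)[seq_len(k)]
}

#' Train the four-model NPP ensemble
#'
#' Fits the random-forest, gradient-boosting, calibrated linear-SVM and
#' minimal-tree models to labeled feature matrices. Performance is first
#' estimated by stratified k-fold cross-validation (default 6-fold):
#' within each fold the four models are fitted on the training split
#' (with the minimal-tree feature subset re-selected from that split
#' only, to keep the estimate free of selection leakage) and scored on
#' the held-out split; held-out accuracy, precision, recall and MCC (at
#' probability 0.5) and AUC are averaged over folds. The final models
#' and the reported minimal subset are then refitted on all data.
#'
#' @param pos,neg Feature tibbles from [extract_features()] for positive
#'   (NPP) and negative training sequences.
#' @param seed Integer seed; the single source of randomness (fold
#'   assignment, forests, feature selection).
#' @param folds Number of cross-validation folds (default 6).
#' @param k_minimal Size of the minimal-tree feature subset (default 20).
#' @param thresholds Named per-model probability thresholds (see
#'   [default_thresholds()]).
#' @param num_trees,nrounds,cost Model hyperparameters: forest size,
#'   boosting rounds, SVM cost.
#' @return An object of class `nppred_bundle` holding the four models, the
#'   thresholds, the feature catalog (names + version), the minimal
#'   feature subset, the seed and the per-model cross-validation metrics
#'   (see [tidy.nppred_bundle()]).
#' @export
npp_train <- function(pos, neg, seed = 1L, folds = 6L, k_minimal = 20L,
                      thresholds = default_thresholds(),
                      num_trees = 300L, nrounds = 150L, cost = 1) {
  stopifnot(nrow(pos) > 0, nrow(neg) > 0)
  stopifnot(all(MODEL_NAMES %in% names(thresholds)),
            all(thresholds > 0 & thresholds < 1))
  check_catalog(pos); check_catalog(neg)
  catalog <- setdiff(colnames(pos), "id")
  if (!identical(catalog, setdiff(colnames(neg), "id"))) {
    stop("positive and negative feature tables disagree on feature order",
         call. = FALSE)
  }
  x <- rbind(feature_matrix(pos, catalog), feature_matrix(neg, catalog))
  y <- factor(rep(c("pos", "neg"), c(nrow(pos), nrow(neg))),
              levels = c("neg", "pos"))
  if (min(table(y)) < folds) {
    stop("need at least `folds` examples per class", call. = FALSE)
  }

  fold_id <- withr::with_seed(seed, make_folds(y, folds))

  # the minimal-tree feature subset is re-selected inside every fold so
  # the cross-validation estimate carries no selection leakage
  fold_metrics <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- fold_id != f
    fold_minimal <- rank_features(x[tr, , drop = FALSE], y[tr],
                                  k = k_minimal, seed = seed + f)
    models <- fit_all_models(x[tr, , drop = FALSE], y[tr], seed = seed + f,
                             minimal_features = fold_minimal,
                             num_trees = num_trees, nrounds = nrounds,
                             cost = cost)
    purrr::imap_dfr(models, function(m, nm) {
      p <- predict_one_model(m, x[!tr, , drop = FALSE])
      truth <- y[!tr] == "pos"
      cm <- confusion_metrics(tp = sum(p > 0.5 & truth),
                              tn = sum(p <= 0.5 & !truth),
                              fp = sum(p > 0.5 & !truth),
                              fn = sum(p <= 0.5 & truth))
      dplyr::mutate(cm, model = nm, fold = f,
                    auc = auc_score(p, truth), .before = 1)
    })
  })
  cv_metrics <- fold_metrics |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(dplyr::across(c("accuracy", "precision", "recall",
                                     "mcc", "auc"), mean),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$model, MODEL_NAMES))

  minimal_features <- select_minimal_features(pos, neg, k = k_minimal,
                                              seed = seed)
  models <- fit_all_models(x, y, seed = seed,
                           minimal_features = minimal_features,
                           num_trees = num_trees, nrounds = nrounds,
                           cost = cost)

  structure(
    list(
      models = models,
      thresholds = thresholds[MODEL_NAMES],
      feature_names = catalog,
      catalog_version = FEATURE_CATALOG_VERSION,
      minimal_feature_names = minimal_features,
      training_seed = as.integer(seed),
      folds = as.integer(folds),
      n_pos = nrow(pos),
      n_neg = nrow(neg),
      cv_metrics = cv_metrics,
      fold_metrics = fold_metrics
    ),
    class = "nppred_bundle"
  )
}

fit_all_models <- function(x, y, seed, minimal_features, num_trees, nrounds,
                           cost) {
  list(
    random_forest = withr::with_seed(seed + 1L,
      fit_random_forest(x, y, seed = seed + 1L, num_trees = num_trees)),
    gradient_boosting = withr::with_seed(seed + 2L,
      fit_gradient_boosting(x, y, seed = seed + 2L, nrounds = nrounds)),
    linear_svm = withr::with_seed(seed + 3L,
      fit_linear_svm(x, y, seed = seed + 3L, cost = cost)),
    minimal_tree = withr::with_seed(seed + 4L,
      fit_random_forest(x, y, seed = seed + 4L, num_trees = num_trees,
                        feature_names = minimal_features))
  )
}

check_catalog <- function(features) {
  v <- attr(features, "catalog_version")
  if (!is.null(v) && !identical(v, FEATURE_CATALOG_VERSION)) {
    stop("feature catalog version mismatch: table built under '", v,
         "', package provides '", FEATURE_CATALOG_VERSION, "'",
         call. = FALSE)
  }
  invisible(features)
}

#' @export
print.nppred_bundle <- function(x, ...) {
  cat("<nppred_bundle> four-model NPP ensemble\n")
  cat("  trained on", x$n_pos, "positives /", x$n_neg, "negatives,",
      x$folds, "-fold CV, seed", x$training_seed, "\n")
  cat("  catalog:", x$catalog_version, "(", length(x$feature_names),
      "features; minimal subset", length(x$minimal_feature_names), ")\n")
  cat("  thresholds:",
      paste(names(x$thresholds), x$thresholds, sep = " > ", collapse = ", "),
      "\n")
  print(x$cv_metrics)
  invisible(x)
}

#' Score sequences with a trained ensemble
#'
#' @param object An `nppred_bundle` from [npp_train()].
#' @param features A feature tibble from [extract_features()]; its catalog
#'   version and feature names must match the bundle.
#' @param ... Unused.
#' @return A tibble with `id` and the four probability columns
#'   `prob_random_forest`, `prob_gradient_boosting`, `prob_linear_svm`,
#'   `prob_minimal_tree`.
#' @export
predict.nppred_bundle <- function(object, features, ...) {
  v <- attr(features, "catalog_version")
  if (!is.null(v) && !identical(v, object$catalog_version)) {
    stop("feature catalog version mismatch: vectors built under '", v,
         "', bundle trained under '", object$catalog_version, "'",
         call. = FALSE)
  }
  x <- feature_matrix(features, object$feature_names)
  probs <- purrr::map(object$models, predict_one_model, x = x)
  tibble::tibble(
    id = as.character(features$id),
    prob_random_forest = probs$random_forest,
    prob_gradient_boosting = probs$gradient_boosting,
    prob_linear_svm = probs$linear_svm,
    prob_minimal_tree = probs$minimal_tree
  )
}

#' Apply per-model decision thresholds
#'
#' A model calls a sequence positive when its probability is *strictly*
#' greater than the model's threshold; the overall call is positive when
#' at least one of the four models calls positive.
#'
#' @param probs A tibble with the four `prob_*` columns (from
#'   [predict.nppred_bundle()]), or a numeric vector of four
#'   probabilities.
#' @param thresholds Named thresholds (default [default_thresholds()]).
#' @return The input tibble with logical `call_*` columns, `overall_call`
#'   and `n_models_agreeing` appended (or, for a length-4 vector, a
#'   one-row tibble).
#' @export
#' @examples
#' call_positive(c(0.85, 0.10, 0.10, 0.10))
call_positive <- function(probs, thresholds = default_thresholds()) {
  if (is.numeric(probs) && length(probs) == 4L) {
    probs <- tibble::tibble(
      prob_random_forest = probs[1], prob_gradient_boosting = probs[2],
      prob_linear_svm = probs[3], prob_minimal_tree = probs[4]
    )
  }
  stopifnot(all(paste0("prob_", MODEL_NAMES) %in% names(probs)))
  out <- probs
  for (m in MODEL_NAMES) {
    out[[paste0("call_", m)]] <- out[[paste0("prob_", m)]] > thresholds[[m]]
  }
  calls <- as.matrix(out[paste0("call_", MODEL_NAMES)])
  out$overall_call <- rowSums(calls) > 0
  out$n_models_agreeing <- as.integer(rowSums(calls))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-model cross-validation metrics of a trained bundle
#'
#' @param x An `nppred_bundle`.
#' @param ... Unused.
#' @return A tibble with one row per model: fold-averaged accuracy,
#'   precision, recall, MCC and AUC.
#' @export
tidy.nppred_bundle <- function(x, ...) {
  x$cv_metrics
}

#' One-row training summary of a trained bundle
#'
#' @param x An `nppred_bundle`.
#' @param ... Unused.
#' @return A one-row tibble: training-set sizes, folds, seed, catalog
#'   version, and the mean and range of the per-model CV AUC.
#' @export
glance.nppred_bundle <- function(x, ...) {
  tibble::tibble(
    n_pos = x$n_pos, n_neg = x$n_neg, folds = x$folds,
    seed = x$training_seed, catalog_version = x$catalog_version,
    n_minimal_features = length(x$minimal_feature_names),
    mean_cv_auc = mean(x$cv_metrics$auc),
    min_cv_auc = min(x$cv_metrics$auc),
    max_cv_auc = max(x$cv_metrics$auc)
  )
}

# ---- bundle persistence -----------------------------------------------

#' Persist a trained bundle to a directory
#'
#' Serialized models plus a plain-text `manifest.yaml` (catalog version,
#' thresholds, seed, minimal feature subset) so the decision rules are
#' auditable without deserializing the models.
#'
#' @param bundle An `nppred_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "nppred_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # xgboost boosters need their own serializer
  gb_raw <- xgboost::xgb.save.raw(bundle$models$gradient_boosting$fit)
  stripped <- bundle
  stripped$models$gradient_boosting$fit <- NULL
  saveRDS(stripped, file.path(dir, "bundle.rds"))
  writeBin(as.vector(gb_raw), file.path(dir, "gradient_boosting.ubj"))
  manifest <- list(
    package = "nppred",
    catalog_version = bundle$catalog_version,
    thresholds = as.list(bundle$thresholds),
    training_seed = bundle$training_seed,
    folds = bundle$folds,
    n_pos = bundle$n_pos,
    n_neg = bundle$n_neg,
    minimal_feature_names = bundle$minimal_feature_names
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Load a bundle written by [write_bundle()]
#'
#' @param dir Bundle directory.
#' @return An `nppred_bundle`.
#' @export
read_bundle <- function(dir) {
  bundle <- readRDS(file.path(dir, "bundle.rds"))
  raw_path <- file.path(dir, "gradient_boosting.ubj")
  gb_raw <- readBin(raw_path, what = "raw", n = file.size(raw_path))
  bundle$models$gradient_boosting$fit <- xgboost::xgb.load.raw(gb_raw)
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (!identical(manifest$catalog_version, bundle$catalog_version)) {
    stop("bundle manifest disagrees with serialized models", call. = FALSE)
  }
  bundle
}
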