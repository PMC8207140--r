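# Deterministic gradient-boosted tree fit (single thread, fixed params).
xgb_fit <- function(x, y_int, n_class, nrounds = 50, max_depth = 3,
                    eta = 0.3) {
  params <- list(max_depth = max_depth, eta = eta, nthread = 1,
                 verbosity = 0)
  if (n_class > 2L) {
    params$objective <- "multi:softprob"
    params$num_class <- n_class
  } else {
    params$objective <- "binary:logistic"
  }
  dtr <- xgboost::xgb.DMatrix(x, label = y_int)
  xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                     verbose = 0)
}

xgb_prob <- function(model, x, n_class) {
  p <- stats::predict(model, xgboost::xgb.DMatrix(x))
  if (n_class > 2L) {
    matrix(p, ncol = n_class)
  } else {
    cbind(1 - p, p)
  }
}

xgb_gain <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp) > 0) {
    out[imp$Feature] <- imp$Gain
  }
  out
}

#' All-relevant feature selection with shadow features
#'
#' Boruta-style selection: each iteration appends an independently permuted
#' shadow copy of every feature, fits a gradient-boosted tree ensemble, and
#' records a "hit" for every real feature whose importance (gain) exceeds
#' the maximum shadow importance. After `max_iter` iterations each feature's
#' hit count is compared to Binomial(iterations, 0.5) with a two-sided test
#' at level `alpha`: significantly more hits than chance confirms the
#' feature, significantly fewer rejects it, the rest stay tentative.
#' Deterministic for a fixed seed.
#'
#' @param features Gene x motif 0/1 matrix (any numeric features work).
#' @param labels Factor (or coercible) of class labels, >= 2 classes.
#' @param max_iter Number of shadow iterations.
#' @param alpha Two-sided significance level of the hit-count test.
#' @param seed Integer seed.
#' @param nrounds,max_depth Boosting parameters of the internal ensemble.
#' @return A list of class `feature_selection` with `confirmed`,
#'   `tentative`, `rejected` (character vectors partitioning the features),
#'   `hits`, `n_iter`, `importance_history` (iteration x feature gain
#'   matrix) and `importance_scaled` (mean gain rescaled so the top feature
#'   scores 100).
#' @export
shadow_select <- function(features, labels, max_iter = 100, alpha = 0.05,
                          seed = 1, nrounds = 25, max_depth = 3) {
  x <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2L) stop("labels must contain at least 2 classes")
  if (ncol(x) < 1L) stop("need at least one feature")
  if (nrow(x) != length(y)) stop("features and labels disagree in length")
  set.seed(seed)
  n_class <- nlevels(y)
  y_int <- as.integer(y) - 1L
  feats <- colnames(x)
  if (is.null(feats)) feats <- colnames(x) <- paste0("f", seq_len(ncol(x)))
  hits <- stats::setNames(integer(length(feats)), feats)
  history <- matrix(NA_real_, nrow = max_iter, ncol = length(feats),
                    dimnames = list(NULL, feats))
  shadow_names <- paste0("shadow_", feats)
  for (it in seq_len(max_iter)) {
    shadows <- apply(x, 2, sample)
    colnames(shadows) <- shadow_names
    xx <- cbind(x, shadows)
    model <- xgb_fit(xx, y_int, n_class, nrounds = nrounds,
                     max_depth = max_depth)
    gain <- xgb_gain(model, colnames(xx))
    max_shadow <- max(gain[shadow_names])
    real <- gain[feats]
    hits <- hits + as.integer(real > max_shadow)
    history[it, ] <- real
  }
  # two-sided binomial test of hit counts against p = 0.5
  p_hi <- stats::pbinom(hits - 1L, max_iter, 0.5, lower.tail = FALSE)
  p_lo <- stats::pbinom(hits, max_iter, 0.5)
  confirmed <- feats[p_hi <= alpha / 2]
  rejected <- feats[p_lo <= alpha / 2]
  rejected <- setdiff(rejected, confirmed)
  tentative <- setdiff(feats, c(confirmed, rejected))
  mean_imp <- colMeans(history)
  scaled <- if (max(mean_imp) > 0) 100 * mean_imp / max(mean_imp) else mean_imp
  structure(list(confirmed = confirmed, tentative = tentative,
                 rejected = rejected, hits = hits, n_iter = max_iter,
                 alpha = alpha, seed = seed,
                 importance_history = history,
                 importance_scaled = sort(scaled, decreasing = TRUE)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("<feature_selection>", length(x$confirmed), "confirmed,",
      length(x$tentative), "tentative,", length(x$rejected), "rejected",
      "after", x$n_iter, "iterations\n")
  invisible(x)
}

# stratified fold assignment, balanced within class
stratified_folds <- function(y, folds) {
  fold_of <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_of
}

# undersample every class to the minority class size
undersample_idx <- function(y) {
  m <- min(table(y))
  unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    if (length(idx) > m) sample(idx, m) else idx
  }), use.names = FALSE)
}

#' Confusion-matrix enrichment percentages
#'
#' Each cell of a predicted x true confusion matrix expressed as a
#' percentage of its predicted-class (row) total, so each row sums to 100.
#' For five balanced classes, 20% per cell is the chance level. An empty
#' predicted class yields a zero row, flagged in attribute `empty_rows`.
#'
#' @param confusion_counts Predicted x true count matrix.
#' @return Matrix of percentages, same dimnames.
#' @examples
#' enrichment_matrix(matrix(c(26, 52), 1, 2))[1, 1] # 33.33
#' @export
enrichment_matrix <- function(confusion_counts) {
  cc <- as.matrix(confusion_counts)
  if (any(cc < 0)) stop("counts must be nonnegative")
  totals <- rowSums(cc)
  out <- cc / ifelse(totals == 0, 1, totals) * 100
  attr(out, "empty_rows") <- rownames(cc)[totals == 0]
  out
}

#' Macro balanced accuracy from a confusion matrix
#'
#' Mean over classes of (sensitivity + specificity) / 2, computed from a
#' predicted x true count matrix. A constant predictor on balanced binary
#' labels scores exactly 0.5.
#'
#' @param confusion Predicted x true count matrix with matching dimnames.
#' @return The macro balanced accuracy.
#' @export
balanced_accuracy <- function(confusion) {
  balanced_accuracy_from_confusion(as.matrix(confusion))$balanced_accuracy
}

balanced_accuracy_from_confusion <- function(confusion) {
  # confusion: predicted rows x true columns
  classes <- colnames(confusion)
  n <- sum(confusion)
  per_class <- vapply(classes, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[, cl]) - tp
    fp <- sum(confusion[cl, ]) - tp
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    c(sensitivity = sens, specificity = spec)
  }, numeric(2))
  list(per_class = t(per_class),
       balanced_accuracy = mean(colMeans(per_class), na.rm = TRUE))
}

macro_auc <- function(y, probs) {
  # one-vs-rest macro AUC from pooled cross-validated probabilities
  classes <- levels(y)
  if (length(classes) == 2L) {
    r <- pROC::roc(response = y == classes[2], predictor = probs[, 2],
                   quiet = TRUE, direction = "<")
    return(as.numeric(pROC::auc(r)))
  }
  aucs <- vapply(seq_along(classes), function(i) {
    resp <- y == classes[i]
    if (all(resp) || !any(resp)) return(NA_real_)
    r <- pROC::roc(response = resp, predictor = probs[, i], quiet = TRUE,
                   direction = "<")
    as.numeric(pROC::auc(r))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Fit and evaluate an expression-type classifier by cross-validation
#'
#' Classes are undersampled to the minority class size, split into
#' stratified folds, and a gradient-boosted tree model is trained on each
#' training split and evaluated on the held-out fold. The pooled predictions
#' give the confusion matrix (predicted rows x true columns), per-cell
#' enrichment percentages, macro balanced accuracy (mean over classes of
#' (sensitivity + specificity) / 2) and macro one-vs-rest AUC-ROC (plain
#' binary AUC for two classes). Deterministic for a fixed seed.
#'
#' @param features Gene x motif 0/1 matrix.
#' @param labels Class labels (factor or coercible), named or aligned with
#'   `features` rows.
#' @param folds Number of CV folds (default 5).
#' @param undersample Balance classes to the minority size before splitting.
#' @param seed Integer seed.
#' @param feature_subset Optional character vector restricting the feature
#'   columns (e.g. the confirmed set from [shadow_select()]).
#' @param nrounds,max_depth Boosting parameters.
#' @return A list of class `classifier_report`: `confusion`,
#'   `enrichment_pct`, `balanced_accuracy`, `auc_roc`, `per_class`
#'   (sensitivity/specificity), `folds`, `seed`, `n_used`, `fold_of`,
#'   `probabilities`.
#' @export
fit_and_evaluate <- function(features, labels, folds = 5, undersample = TRUE,
                             seed = 1, feature_subset = NULL, nrounds = 50,
                             max_depth = 3) {
  x <- as.matrix(features)
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(x))
    if (length(missing)) stop("unknown feature(s): ",
                              paste(missing, collapse = ", "))
    x <- x[, feature_subset, drop = FALSE]
  }
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(x) == length(y))
  small <- table(y) < folds
  if (any(small)) {
    stop("class '", names(which(small))[1], "' has fewer members than folds")
  }
  set.seed(seed)
  if (undersample) {
    keep <- sort(undersample_idx(y))
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  n_class <- nlevels(y)
  y_int <- as.integer(y) - 1L
  fold_of <- stratified_folds(y, folds)
  probs <- matrix(NA_real_, nrow = length(y), ncol = n_class,
                  dimnames = list(NULL, levels(y)))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    model <- xgb_fit(x[tr, , drop = FALSE], y_int[tr], n_class,
                     nrounds = nrounds, max_depth = max_depth)
    probs[!tr, ] <- xgb_prob(model, x[!tr, , drop = FALSE], n_class)
  }
  pred <- factor(levels(y)[max.col(probs, ties.method = "first")],
                 levels = levels(y))
  confusion <- table(predicted = pred, true = y)
  confusion <- matrix(as.integer(confusion), nrow = n_class,
                      dimnames = list(predicted = levels(y),
                                      true = levels(y)))
  ba <- balanced_accuracy_from_confusion(confusion)
  structure(list(confusion = confusion,
                 enrichment_pct = enrichment_matrix(confusion),
                 balanced_accuracy = ba$balanced_accuracy,
                 per_class = ba$per_class,
                 auc_roc = macro_auc(y, probs),
                 folds = folds, seed = seed, n_used = length(y),
                 fold_of = fold_of, probabilities = probs),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d genes, %d-fold CV\n", x$n_used,
              x$folds))
  cat(sprintf("  balanced accuracy: %.3f   AUC-ROC: %.3f\n",
              x$balanced_accuracy, x$auc_roc))
  print(x$confusion)
  invisible(x)
}

#' Binary responsive-vs-none tissue model
#'
#' Same protocol as [fit_and_evaluate()] restricted to two classes (e.g.
#' Fe-excess responsive vs no-response within one tissue), reporting the
#' plain binary AUC.
#'
#' @inheritParams fit_and_evaluate
#' @param labels Two-class labels.
#' @return A `classifier_report`.
#' @export
binary_tissue_model <- function(features, labels, folds = 5,
                                undersample = TRUE, seed = 1,
                                feature_subset = NULL, nrounds = 50,
                                max_depth = 3) {
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2L) stop("binary_tissue_model requires exactly 2 classes")
  fit_and_evaluate(features, y, folds = folds, undersample = undersample,
                   seed = seed, feature_subset = feature_subset,
                   nrounds = nrounds, max_depth = max_depth)
}

#' Serialize a classifier report to JSON
#'
#' @param report A `classifier_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(confusion = report$confusion,
              enrichment_pct = round(report$enrichment_pct, 2),
              balanced_accuracy = report$balanced_accuracy,
              auc_roc = report$auc_roc,
              per_class = report$per_class,
              folds = report$folds, seed = report$seed,
              n_used = report$n_used, fold_of = report$fold_of)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
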