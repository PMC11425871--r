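# Classifier training and repeated cross-validation evaluation: KNN (K=8),
# SVM with Gaussian kernel, and logistic regression over the 9-feature
# vectors, with rank-based AUC, step-interpolated AUPR and best-F metrics.

#' Classifier configuration
#'
#' @param method "KNN", "SVM" or "LR". All three emit a continuous score in
#'   \[0, 1\]: KNN the positive fraction among the K nearest neighbours,
#'   SVM the decision value mapped through a logistic link fitted on the
#'   training fold (Platt scaling), LR the predicted probability.
#' @param knn_k neighbourhood size (default 8).
#' @param seed integer seed (used by the SVM's internal calibration).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(method = c("KNN", "SVM", "LR"), knn_k = 8L,
                              seed = 1L) {
  method <- match.arg(method)
  if (knn_k < 1L) abort_input("knn_k must be >= 1")
  structure(list(method = method, knn_k = as.integer(knn_k),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Cross-validation scheme
#'
#' @param kind "kfold" or "loo".
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats of the fold split (default 100; ignored for
#'   LOO, which is deterministic and run once).
#' @param stratified preserve the class ratio within each fold (±1 sample).
#' @param seed integer seed for the fold splits.
#' @return A `cv_scheme` list.
#' @export
cv_scheme <- function(kind = c("kfold", "loo"), n_folds = 5L,
                      n_repeats = 100L, stratified = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n_folds = as.integer(n_folds),
                 n_repeats = if (kind == "loo") 1L else as.integer(n_repeats),
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_scheme")
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so fold class ratios differ by at most one sample.
.make_folds <- function(y, n_folds, stratified, seed) {
  n <- length(y)
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample(n)] <- rep_len(seq_len(n_folds), n)
    }
    fold
  })
}

# z-score standardisation fitted on the training rows only
.fit_scaler <- function(x_train) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
.apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# ---- individual learners: train on (xtr, ytr), score xte in [0, 1] ----

.score_knn <- function(xtr, ytr, xte, k) {
  if (nrow(xtr) < k) abort_input("training fold smaller than knn_k")
  # squared Euclidean distances test x train
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * xte %*% t(xtr)
  apply(d2, 1L, function(row) {
    nb <- order(row, seq_along(row))[seq_len(k)] # index breaks distance ties
    mean(ytr[nb])
  })
}

.score_svm <- function(xtr, ytr, xte, seed) {
  fit <- with_seed(seed, e1071::svm(xtr, factor(ytr, levels = c(0, 1)),
                                    kernel = "radial", probability = TRUE))
  pr <- with_seed(seed, stats::predict(fit, xte, probability = TRUE))
  unname(attr(pr, "probabilities")[, "1"])
}

.score_lr <- function(xtr, ytr, xte) {
  colnames(xtr) <- colnames(xte) <- paste0("f", seq_len(ncol(xtr)))
  df <- as.data.frame(xtr)
  fit <- suppressWarnings(stats::glm(ytr ~ ., data = cbind(ytr = ytr, df),
                                     family = stats::binomial()))
  as.numeric(suppressWarnings(stats::predict(fit, as.data.frame(xte),
                                             type = "response")))
}

.score_fold <- function(clf, xtr, ytr, xte, fold_seed) {
  switch(clf$method,
         KNN = .score_knn(xtr, ytr, xte, clf$knn_k),
         SVM = .score_svm(xtr, ytr, xte, fold_seed),
         LR = .score_lr(xtr, ytr, xte))
}

#' Repeated cross-validation out-of-fold scores
#'
#' Every sample is scored exactly once per repeat by a model that never saw
#' it. Feature standardisation (z-score) is fitted within each training
#' fold and applied to its test fold. Deterministic given the scheme and
#' classifier seeds.
#'
#' @param features a `feature_table` or list(x, y) from [feature_matrix()].
#' @param clf a [classifier_config()].
#' @param scheme a [cv_scheme()].
#' @param standardize z-score features within training folds (default TRUE).
#' @return List of numeric out-of-fold score vectors, one per repeat, each
#'   parallel to the rows of `features`; attribute `labels` carries y.
#' @export
cross_validate <- function(features, clf, scheme, standardize = TRUE) {
  fm <- if (inherits(features, "feature_table")) feature_matrix(features)
        else features
  x <- fm$x
  y <- fm$y
  n <- length(y)
  if (length(unique(y)) < 2L)
    abort_input("cross-validation requires both classes present")
  n_folds <- if (scheme$kind == "loo") n else scheme$n_folds
  reps <- lapply(seq_len(scheme$n_repeats), function(rep_i) {
    fold <- if (scheme$kind == "loo") seq_len(n)
            else .make_folds(y, n_folds, scheme$stratified,
                             seed = derive_seed(scheme$seed,
                                                paste0("rep", rep_i)))
    oof <- numeric(n)
    for (f in seq_len(n_folds)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      if (length(unique(y[tr])) < 2L)
        abort_input("single-class training fold; dataset too small/imbalanced")
      xtr <- x[tr, , drop = FALSE]
      xte <- x[te, , drop = FALSE]
      if (standardize) {
        sc <- .fit_scaler(xtr)
        xtr <- .apply_scaler(xtr, sc)
        xte <- .apply_scaler(xte, sc)
      }
      oof[te] <- .score_fold(clf, xtr, y[tr], xte,
                             fold_seed = derive_seed(clf$seed,
                                                     sprintf("r%df%d", rep_i, f)))
    }
    oof
  })
  attr(reps, "labels") <- y
  reps
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' Ties contribute one half. Curve points are the (FPR, TPR) pairs at every
#' distinct score threshold, descending, bracketed by (0,0) and (1,1).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) true labels; both classes required.
#' @return list(auc, curve = data.frame(fpr, tpr, threshold)).
#' @export
roc_auc <- function(scores, labels) {
  y <- as.integer(labels)
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  if (np == 0L || nn == 0L) abort_input("both classes required for ROC")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / np, 1.0)
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / nn, 1.0)
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                      threshold = c(Inf, thr, -Inf))
  list(auc = auc, curve = curve)
}

#' Precision-recall metrics at the best F-measure cutoff
#'
#' Candidate cutoffs are the distinct score values; a sample is called
#' positive when its score is >= the cutoff. AUPR is the step-wise
#' interpolation of the PR curve (sum of precision times recall
#' increment over descending cutoffs). The reported cutoff maximises
#' F1 = 2PR/(P+R); ties go to the lowest cutoff.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) true labels; positives required.
#' @return list(aupr, precision, recall, f1, cutoff,
#'   curve = data.frame(recall, precision, threshold)).
#' @export
pr_metrics <- function(scores, labels) {
  y <- as.integer(labels)
  np <- sum(y == 1L)
  if (np == 0L) abort_input("no positive labels; PR metrics undefined")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & y == 1L), 1.0)
  pp <- vapply(thr, function(t) sum(scores >= t), 1.0)
  precision <- tp / pp
  recall <- tp / np
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  aupr <- sum(diff(c(0, recall)) * precision)
  # ties on F1 -> lowest cutoff (last index in descending threshold order)
  best <- max(which(f1 == max(f1)))
  list(aupr = aupr, precision = precision[best], recall = recall[best],
       f1 = f1[best], cutoff = thr[best],
       curve = data.frame(recall = recall, precision = precision,
                          threshold = thr))
}

#' Evaluate classifiers on a feature table
#'
#' Runs [cross_validate()] for each requested method and summarises:
#' per-repeat pooled out-of-fold metrics, their across-repeat mean and sd,
#' and ROC/PR curves from the first repeat.
#'
#' @param features a `feature_table` or list(x, y).
#' @param methods classifier names (default all three).
#' @param scheme a [cv_scheme()].
#' @param knn_k,seed forwarded to [classifier_config()].
#' @return An `eval_report`: per-method list with `per_repeat`
#'   (data.frame of auc/aupr/precision/recall/f1/cutoff), `mean`, `sd`,
#'   `oof_scores` (first repeat), `roc`, `pr`; attribute `labels`.
#' @export
evaluate_methods <- function(features, methods = c("KNN", "SVM", "LR"),
                             scheme = cv_scheme(), knn_k = 8L, seed = 1L) {
  out <- lapply(methods, function(m) {
    clf <- classifier_config(m, knn_k = knn_k,
                             seed = derive_seed(seed, paste0("clf_", m)))
    reps <- cross_validate(features, clf, scheme)
    y <- attr(reps, "labels")
    per <- do.call(rbind, lapply(reps, function(s) {
      roc <- roc_auc(s, y)
      pr <- pr_metrics(s, y)
      data.frame(auc = roc$auc, aupr = pr$aupr, precision = pr$precision,
                 recall = pr$recall, f1 = pr$f1, cutoff = pr$cutoff)
    }))
    list(per_repeat = per,
         mean = colMeans(per), sd = apply(per, 2, stats::sd),
         oof_scores = reps[[1]],
         roc = roc_auc(reps[[1]], y)$curve,
         pr = pr_metrics(reps[[1]], y)$curve)
  })
  names(out) <- methods
  attr(out, "labels") <- if (inherits(features, "feature_table"))
    feature_matrix(features)$y else features$y
  class(out) <- "eval_report"
  out
}

#' Score a baseline-only predictor
#'
#' A fixed per-sample score table involves no training, so its metrics are
#' identical under any cross-validation scheme; they are computed once on
#' the full sample.
#'
#' @param scores numeric baseline scores, parallel to labels.
#' @param labels 0/1 labels.
#' @return list(auc, aupr, precision, recall, f1, cutoff, roc, pr).
#' @export
baseline_metrics <- function(scores, labels) {
  roc <- roc_auc(scores, labels)
  pr <- pr_metrics(scores, labels)
  list(auc = roc$auc, aupr = pr$aupr, precision = pr$precision,
       recall = pr$recall, f1 = pr$f1, cutoff = pr$cutoff,
       roc = roc$curve, pr = pr$curve)
}

#' Compare 3D-augmented methods against the baseline
#'
#' @param baseline_scores numeric baseline scores for the same samples (and
#'   order) the report was built on.
#' @param report an `eval_report` from [evaluate_methods()].
#' @param setting label for the comparison row (e.g. "surrogate,5fold").
#' @return data.frame with one baseline row and one row per method:
#'   Setting, Method, Precision, Recall, F1, AUPR, AUC, dAUC_mean, dAUC_sd,
#'   dAUPR_mean, dAUPR_sd.
#' @export
compare_methods <- function(baseline_scores, report, setting = "surrogate") {
  y <- attr(report, "labels")
  if (length(baseline_scores) != length(y))
    abort_input("baseline scores and report cover different sample sets")
  base <- baseline_metrics(baseline_scores, y)
  rows <- list(data.frame(
    Setting = setting, Method = "baseline",
    Precision = base$precision, Recall = base$recall, F1 = base$f1,
    AUPR = base$aupr, AUC = base$auc,
    dAUC_mean = 0, dAUC_sd = 0, dAUPR_mean = 0, dAUPR_sd = 0))
  for (m in names(report)) {
    per <- report[[m]]$per_repeat
    rows[[m]] <- data.frame(
      Setting = setting, Method = paste0("Plus3D-", m),
      Precision = mean(per$precision), Recall = mean(per$recall),
      F1 = mean(per$f1), AUPR = mean(per$aupr), AUC = mean(per$auc),
      dAUC_mean = mean(per$auc - base$auc),
      dAUC_sd = stats::sd(per$auc - base$auc),
      dAUPR_mean = mean(per$aupr - base$aupr),
      dAUPR_sd = stats::sd(per$aupr - base$aupr))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
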