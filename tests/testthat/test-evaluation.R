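# Cross-validation mechanics, metric definitions and method comparison.

sim_features <- function(n, signal = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  eta <- signal * x[, 1]
  y <- rbinom(n, 1, plogis(eta))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(x = x, y = y)
}

test_that("k-fold test sets partition the samples with stratification", {
  fm <- sim_features(10)
  fm$y <- rep(c(0L, 1L), 5)
  scheme <- cv_scheme("kfold", n_folds = 5, n_repeats = 2, seed = 3)
  fold <- neo3d:::.make_folds(fm$y, 5, TRUE, seed = 42)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(unname(table(fold)), rep(2L, 5), ignore_attr = TRUE)
  # each fold holds one positive and one negative (perfect stratification)
  expect_true(all(tapply(fm$y, fold, sum) == 1))

  reps <- cross_validate(fm, classifier_config("LR"), scheme)
  expect_length(reps, 2)
  expect_true(all(is.finite(reps[[1]])))
})

test_that("LOO scores every sample once with singleton test sets", {
  fm <- sim_features(12, signal = 2)
  scheme <- cv_scheme("loo")
  expect_equal(scheme$n_repeats, 1L)
  reps <- cross_validate(fm, classifier_config("LR"), scheme)
  expect_length(reps, 1)
  expect_length(reps[[1]], 12)
  # LOO is deterministic for LR: identical across invocations
  reps2 <- cross_validate(fm, classifier_config("LR"), cv_scheme("loo"))
  expect_identical(reps[[1]], reps2[[1]])
})

test_that("KNN scores are positive-neighbour fractions", {
  xtr <- matrix(c(0, 0, 0, 0, 0, 0, 0, 0, 9, 9), ncol = 1)
  ytr <- c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L)
  s <- neo3d:::.score_knn(xtr, ytr, matrix(0.1), k = 8)
  expect_equal(s, 1.0) # all 8 nearest neighbours positive
  s2 <- neo3d:::.score_knn(xtr, ytr, matrix(8.9), k = 8)
  expect_equal(s2, 6 / 8)
})

test_that("single-class data are rejected", {
  fm <- sim_features(10)
  fm$y <- rep(1L, 10)
  expect_error(cross_validate(fm, classifier_config("LR"), cv_scheme()),
               "both classes")
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  expect_error(pr_metrics(runif(5), rep(0, 5)), "no positive")
})

test_that("AUC hits its analytic endpoints", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0, 1, 0, 1))$auc, 0.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
})

test_that("rank-formula AUC equals trapezoidal ROC integration", {
  set.seed(7)
  for (i in 1:100) {
    inst <- random_instance(sample(10:200, 1))
    got <- roc_auc(inst$scores, inst$labels)
    trap <- sum(diff(got$curve$fpr) *
                  (head(got$curve$tpr, -1) + tail(got$curve$tpr, -1)) / 2)
    expect_equal(got$auc, trap, tolerance = 1e-9)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    inst <- random_instance(100)
    ref <- as.numeric(pROC::auc(pROC::roc(inst$labels, inst$scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(inst$scores, inst$labels)$auc, ref,
                 tolerance = 1e-12)
  }
})

test_that("best-F cutoff equals exhaustive threshold search", {
  brute_best_f <- function(scores, labels) {
    best <- c(f1 = -1, cutoff = NA)
    for (t in sort(unique(scores))) { # ascending: later wins ties -> lowest
      pred <- scores >= t
      tp <- sum(pred & labels == 1)
      P <- tp / sum(pred)
      R <- tp / sum(labels == 1)
      f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
      if (f1 > best["f1"] ||
          (f1 == best["f1"] && t < best["cutoff"])) best <- c(f1 = f1, cutoff = t)
    }
    best
  }
  set.seed(9)
  for (i in 1:100) {
    inst <- random_instance(sample(10:120, 1))
    got <- pr_metrics(inst$scores, inst$labels)
    ref <- brute_best_f(inst$scores, inst$labels)
    expect_equal(got$f1, unname(ref["f1"]), tolerance = 1e-12)
    expect_equal(got$cutoff, unname(ref["cutoff"]))
  }
})

test_that("worked PR examples match hand arithmetic", {
  got <- pr_metrics(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_equal(got$f1, 1.0)
  expect_equal(got$cutoff, 0.8)

  allpos <- pr_metrics(c(0.3, 0.9, 0.5), c(1, 1, 1))
  expect_equal(c(allpos$precision, allpos$recall, allpos$f1), c(1, 1, 1))
  expect_equal(allpos$cutoff, 0.3)

  tied <- pr_metrics(c(0.7, 0.7, 0.7), c(1, 0, 1))
  expect_equal(tied$precision, 2 / 3)
  expect_equal(tied$recall, 1)
  expect_equal(tied$f1, 0.8)
})

test_that("an uninformative baseline degenerates to recall 1, precision = prevalence", {
  set.seed(33)
  y <- rbinom(200, 1, 0.4)
  s <- rep(0.5, 200) # no label information: the single cutoff admits all
  got <- pr_metrics(s, y)
  expect_equal(got$recall, 1.0)
  expect_equal(got$precision, mean(y))
  expect_equal(got$cutoff, 0.5)
  expect_equal(roc_auc(s, y)$auc, 0.5)
})

test_that("label permutation drives cross-validated AUC to chance", {
  fm <- sim_features(400, signal = 2, seed = 5)
  set.seed(99)
  fm$y <- sample(fm$y)
  scheme <- cv_scheme("kfold", 5, n_repeats = 3, seed = 17)
  for (m in c("KNN", "LR")) {
    reps <- cross_validate(fm, classifier_config(m), scheme)
    aucs <- vapply(reps, function(s) roc_auc(s, fm$y)$auc, 1.0)
    expect_gt(mean(aucs), 0.40)
    expect_lt(mean(aucs), 0.60)
  }
})

test_that("repeat aggregation tightens with more repeats on fixed signal", {
  fm <- sim_features(300, signal = 1.5, seed = 8)
  rep10 <- evaluate_methods(fm, "LR", cv_scheme("kfold", 5, 10, seed = 4))
  expect_lt(rep10$LR$sd[["auc"]], 0.05)
  expect_gt(rep10$LR$mean[["auc"]], 0.6)
})

test_that("comparison against a method's own scores gives zero deltas", {
  fm <- sim_features(120, signal = 2, seed = 10)
  report <- evaluate_methods(fm, "LR", cv_scheme("kfold", 5, 2, seed = 6))
  own <- report$LR$oof_scores
  # degenerate comparison: baseline identical to the first repeat's scores
  cmp <- compare_methods(own, report, setting = "self")
  base_auc <- cmp$AUC[cmp$Method == "baseline"]
  expect_equal(cmp$dAUC_mean[cmp$Method == "Plus3D-LR"],
               mean(report$LR$per_repeat$auc) - base_auc, tolerance = 1e-12)
  expect_error(compare_methods(own[-1], report), "different sample")
})

test_that("SVM scores are deterministic probabilities in [0, 1]", {
  fm <- sim_features(80, signal = 2, seed = 12)
  scheme <- cv_scheme("kfold", 4, n_repeats = 2, seed = 13)
  r1 <- cross_validate(fm, classifier_config("SVM", seed = 5), scheme)
  r2 <- cross_validate(fm, classifier_config("SVM", seed = 5), scheme)
  expect_identical(r1, r2)
  expect_true(all(unlist(r1) >= 0 & unlist(r1) <= 1))
})
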