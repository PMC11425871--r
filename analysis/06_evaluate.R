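#!/usr/bin/env Rscript
# Stage 6: repeated cross-validation evaluation.
#
# KNN (K = 8), SVM (Gaussian kernel) and logistic regression on the
# 9 features under 20 repeats of stratified 5-fold CV, compared with the
# fixed baseline score; metrics at the best F-measure cutoff plus AUPR and
# AUC, averaged across repeats.
source("analysis/00_config.R")

ft <- read_feature_tsv(file.path(cfg$outdir, "features.tsv"))
scheme <- cv_scheme(cfg$cv_kind, cfg$n_folds, cfg$n_repeats,
                    seed = derive_seed(cfg$seed, "cv"))
report <- evaluate_methods(ft, c("KNN", "SVM", "LR"), scheme,
                           seed = derive_seed(cfg$seed, "clf"))
comparison <- compare_methods(ft$score, report,
                              setting = paste("surrogate", cfg$cv_kind,
                                              sep = ","))
utils::write.table(format(comparison, digits = 4),
                   file.path(cfg$outdir, "metrics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("Method comparison (means over", cfg$n_repeats, "repeats):\n")
print(comparison[, c("Method", "Precision", "Recall", "F1", "AUPR", "AUC",
                     "dAUC_mean", "dAUC_sd")], digits = 3, row.names = FALSE)

roc_path <- file.path(cfg$outdir, "roc_curves.tsv")
curves <- do.call(rbind, lapply(names(report), function(m)
  cbind(method = paste0("Plus3D-", m), report[[m]]$roc)))
y <- feature_matrix(ft)$y
curves <- rbind(curves, cbind(method = "baseline",
                              roc_auc(ft$score, y)$curve))
utils::write.table(curves, roc_path, sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("ROC curve points written to", roc_path, "\n")
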