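#!/usr/bin/env Rscript
# Stage 2 - screen the acoustic marker.
#
# Trains one linear SVM per syllable and gender on the screening cohort's
# 15-feature session table, labeled by the binary perceptual outcome of that
# syllable. Emits the two 15 x 12 predictor-weight ("LPC") matrices, the
# mean-|weight| marker ranking, the gender comparison of weights, and the
# per-model cross-validation metrics.
source("analysis/00_common.R")

screening <- simulate_cohort(cohort_config("screening", seed = SEED_SCREEN))
res <- screen_markers(screening$sessions, screening$perception,
                      folds = 10, seed = SEED_MODEL)

for (g in names(res$lpc))
  save_table(data.frame(feature = rownames(res$lpc[[g]]), res$lpc[[g]],
                        check.names = FALSE),
             paste0("lpc_", g))
save_table(res$ranking$ranking, "marker_ranking")
save_table(res$gender_comparison, "lpc_gender_comparison")

metrics <- do.call(rbind, lapply(names(res$models), function(g) {
  do.call(rbind, lapply(names(res$models[[g]]), function(s) {
    m <- res$models[[g]][[s]]
    data.frame(gender = g, syllable = s, n_sv = m$n_sv,
               cv_accuracy = m$cv$accuracy, cv_auc = m$cv$auc,
               cv_sensitivity = m$cv$sensitivity,
               cv_specificity = m$cv$specificity,
               cv_ppv = m$cv$ppv, cv_npv = m$cv$npv)
  }))
}))
save_table(metrics, "svm_cv_metrics")

# generalization: evaluate the trained models on the validation cohort's
# pre-operative sessions (screening = training set, validation = test set)
validation <- simulate_cohort(cohort_config("validation", seed = SEED_VALID))
gen <- do.call(rbind, lapply(names(res$models), function(g) {
  do.call(rbind, lapply(names(res$models[[g]]), function(s) {
    j <- label_join(validation$sessions, validation$perception, s)
    if (is.null(j[[g]]) || length(unique(j[[g]]$y)) < 2) return(NULL)
    met <- evaluate_model(res$models[[g]][[s]], j[[g]]$x, j[[g]]$y)
    data.frame(gender = g, syllable = s, test_accuracy = met$accuracy,
               test_auc = met$auc)
  }))
}))
save_table(gen, "svm_generalization")

cat("dominant marker:", res$ranking$dominant, "\n")
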