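#!/usr/bin/env Rscript
# Stage 5 - ROC diagnostics on merged pre-operative data.
#
# Merges the pre-operative sessions of both cohorts and evaluates FCR as a
# diagnostic score for the two stage dichotomies: T3-4 vs T0-2 and
# T1-4 vs T0, reporting AUC with confidence interval and the Youden-optimal
# cutoff with its sensitivity/specificity.
source("analysis/00_common.R")

screening <- simulate_cohort(cohort_config("screening", seed = SEED_SCREEN))
validation <- simulate_cohort(cohort_config("validation", seed = SEED_VALID))
shared <- intersect(names(screening$sessions), names(validation$sessions))
merged <- rbind(screening$sessions[, shared], validation$sessions[, shared])
merged <- merged[merged$timepoint == "pre", ]

rocs <- stage_rocs(merged)
summarize <- function(r, name) data.frame(
  dichotomy = name, auc = r$auc, ci_lo = r$ci[1], ci_hi = r$ci[2],
  cutoff = r$cutoff, sensitivity = r$sensitivity, specificity = r$specificity,
  n_pos = r$n_pos, n_neg = r$n_neg)
save_table(rbind(summarize(rocs$t34_vs_t02, "T3-4 vs T0-2"),
                 summarize(rocs$t14_vs_t0, "T1-4 vs T0")), "stage_roc_summary")
save_table(data.frame(dichotomy = "T3-4 vs T0-2", rocs$t34_vs_t02$curve),
           "roc_curve_t34_vs_t02")
save_table(data.frame(dichotomy = "T1-4 vs T0", rocs$t14_vs_t0$curve),
           "roc_curve_t14_vs_t0")

cat(sprintf("T3-4 vs T0-2: AUC %.3f, cutoff %.3f | T1-4 vs T0: AUC %.3f, cutoff %.3f\n",
            rocs$t34_vs_t02$auc, rocs$t34_vs_t02$cutoff,
            rocs$t14_vs_t0$auc, rocs$t14_vs_t0$cutoff))
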