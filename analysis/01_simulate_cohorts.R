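#!/usr/bin/env Rscript
# Stage 1 - simulate the two cohorts.
#
# Screening cohort: pre-operative sessions of 120 patients plus 36 healthy
# controls, used to train the per-syllable SVMs. Validation cohort: 33
# patients measured pre- and post-operatively (one late-enrolled dropout),
# with perceptual outcomes and 30-item questionnaires bundled per session.
source("analysis/00_common.R")

screening <- simulate_cohort(cohort_config("screening", seed = SEED_SCREEN))
validation <- simulate_cohort(cohort_config("validation", seed = SEED_VALID))

save_table(screening$sessions, "screening_sessions")
save_table(screening$perception, "screening_perception")
save_table(validation$sessions, "validation_sessions")
save_table(validation$perception, "validation_perception")
save_table(as.data.frame(validation$shi), "validation_shi_items")
save_table(validation$roster, "validation_roster")

cat(sprintf("screening: %d sessions | validation: %d sessions, follow-up %.0f%%\n",
            nrow(screening$sessions), nrow(validation$sessions),
            followup_rate(validation)))
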