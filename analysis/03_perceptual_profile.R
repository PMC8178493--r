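#!/usr/bin/env Rscript
# Stage 3 - perceptual outcome profile of the screening cohort.
#
# Percent consonants correct (PCC) overall, by consonant place group and by
# gender x place, mirroring the screening-stage perceptual analysis.
source("analysis/00_common.R")

screening <- simulate_cohort(cohort_config("screening", seed = SEED_SCREEN))

save_table(pcc(screening$perception, "overall"), "pcc_overall")
save_table(pcc(screening$perception, "place"), "pcc_by_place")
save_table(pcc(screening$perception, "gender_place"), "pcc_by_gender_place")
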