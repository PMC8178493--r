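#!/usr/bin/env Rscript
# Stage 4 - clinical validation of the screened marker (FCR).
#
# On the validation cohort: cohort balance checks, SHI questionnaire
# reliability, FCR-vs-SHI correlation, pre-operative stage trend, a two-way
# ANOVA of pre-operative FCR (T class x gender), and the longitudinal pre/post
# mixed model with per-stage contrasts.
source("analysis/00_common.R")

validation <- simulate_cohort(cohort_config("validation", seed = SEED_VALID))
sessions <- validation$sessions

## cohort balance (gender vs reconstruction / flap / T class / resection)
bal <- balance_table(validation$roster)
save_table(do.call(rbind, lapply(names(bal), function(k)
  data.frame(variable = k,
             test = if (is.null(bal[[k]]$table)) "two-sample t" else "Fisher exact",
             p = bal[[k]]$p))), "cohort_balance")

## SHI reliability and totals
alphas <- shi_reliability(validation$shi)
save_table(data.frame(domain = names(alphas), cronbach_alpha = unlist(alphas)),
           "shi_reliability")
totals <- t(apply(validation$shi, 1, function(it) unlist(score_shi(it))))
shi_tot <- data.frame(session = rownames(totals), totals)
save_table(shi_tot, "shi_totals")

## pre-op FCR vs SHI total correlation
pre <- sessions[sessions$timepoint == "pre", ]
pre_tot <- shi_tot$total[match(pre$session, shi_tot$session)]
corr <- pearson_test(pre$FCR, pre_tot)
save_table(corr, "fcr_shi_correlation")

## pre-op trend of FCR over T1-T4 (overall and by gender)
trend_row <- function(group, y, t) {
  tr <- trend_regression(y, t)
  data.frame(group = group, slope = tr$slope, ci_lo = tr$ci[1], ci_hi = tr$ci[2],
             p = tr$p, r_squared = tr$r_squared, n = tr$n)
}
trends <- rbind(
  trend_row("all", pre$FCR, pre$tclass),
  trend_row("male", pre$FCR[pre$gender == "male"], pre$tclass[pre$gender == "male"]),
  trend_row("female", pre$FCR[pre$gender == "female"], pre$tclass[pre$gender == "female"]))
save_table(trends, "fcr_stage_trend")

## two-way ANOVA of pre-op FCR: T class x gender
an <- two_way_anova(pre$FCR, paste0("T", pre$tclass), pre$gender)
save_table(an, "preop_fcr_anova")

## longitudinal pre/post mixed models (T class, then resection extent)
mm_t <- mixed_prepost(sessions, factor = "tclass")
save_table(mm_t$tests, "mixed_time_by_tclass_tests")
save_table(mm_t$pairwise, "mixed_time_by_tclass_pairwise")
sessions$resection <- as.character(sessions$resection)
mm_r <- mixed_prepost(sessions[sessions$tclass > 0, ], factor = "resection")
save_table(mm_r$tests, "mixed_time_by_resection_tests")
save_table(mm_r$pairwise, "mixed_time_by_resection_pairwise")

cat(sprintf("alpha(total)=%.3f | r(FCR,SHI)=%.2f | trend slope=%.3f\n",
            alphas[["total"]], corr$statistic, trends$slope[1]))
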