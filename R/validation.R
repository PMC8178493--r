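#' Score the 30-item speech questionnaire
#'
#' Computes the total and the two 14-item subdomain scores from the fixed
#' item-domain map (items 1-14 speech, 15-28 psychosocial; the two remaining
#' general items enter only the total). The map is configuration data.
#'
#' @param items numeric vector of 30 item scores on the 0-`scale_max` scale.
#' @param scale_max top of the item scale (default 4).
#' @param speech_items,psychosocial_items item indices of the two subdomains.
#' @return list with `total`, `speech`, `psychosocial`.
#' @export
score_shi <- function(items, scale_max = 4,
                      speech_items = 1:14, psychosocial_items = 15:28) {
  if (length(items) != 30) stop("expected 30 item scores, got ", length(items))
  if (any(!is.finite(items)) || any(items < 0) || any(items > scale_max))
    stop("item scores must lie in [0, ", scale_max, "]")
  if (length(intersect(speech_items, psychosocial_items)) > 0)
    stop("subdomain item sets must be disjoint")
  list(total = sum(items),
       speech = sum(items[speech_items]),
       psychosocial = sum(items[psychosocial_items]))
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} with sample variances of
#' the k items and of the row totals. Returns NA with a warning when the total
#' variance is zero.
#'
#' @param items n x k matrix of item scores (rows = respondents).
#' @return scalar alpha (NA if undefined).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (nrow(items) < 2 || ncol(items) < 2)
    stop("need at least 2 respondents and 2 items")
  k <- ncol(items)
  tot_var <- stats::var(rowSums(items))
  if (tot_var == 0) {
    warning("zero total-score variance: alpha undefined")
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / tot_var)
}

#' Questionnaire reliability per domain
#' @param shi_mat sessions x 30 item matrix.
#' @param speech_items,psychosocial_items subdomain item indices.
#' @return named vector: alpha for total (all 30 items), speech, psychosocial.
#' @export
shi_reliability <- function(shi_mat, speech_items = 1:14, psychosocial_items = 15:28) {
  c(total = cronbach_alpha(shi_mat),
    speech = cronbach_alpha(shi_mat[, speech_items, drop = FALSE]),
    psychosocial = cronbach_alpha(shi_mat[, psychosocial_items, drop = FALSE]))
}

#' @name stat-tests
#' @title Elementary statistical tests with a uniform tidy return
#' @description Thin wrappers around the standard tests used throughout the
#'   validation stage; each returns a one-row data.frame with `statistic`, `p`
#'   and `n`. Pearson and t tests on zero-variance input return missing values
#'   rather than erroring. The Mann-Whitney test is exact for small untied
#'   samples and uses the tie-corrected normal approximation otherwise
#'   (stats::wilcox.test semantics); Fisher's test is two-sided by summation of
#'   tables no more probable than the observed one.
NULL

#' @param x,y numeric samples.
#' @rdname stat-tests
#' @export
pearson_test <- function(x, y) {
  n <- sum(stats::complete.cases(x, y))
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
    return(data.frame(statistic = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(statistic = unname(ct$estimate), p = ct$p.value, n = n)
}

#' @param alternative "two.sided", "less" or "greater".
#' @rdname stat-tests
#' @export
t_test2 <- function(x, y, alternative = "two.sided") {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(data.frame(statistic = NA_real_, p = NA_real_, n = length(x) + length(y)))
  tt <- stats::t.test(x, y, alternative = alternative)
  data.frame(statistic = unname(tt$statistic), p = tt$p.value,
             n = length(x) + length(y))
}

#' @rdname stat-tests
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  wt <- stats::wilcox.test(x, y, alternative = alternative)
  data.frame(statistic = unname(wt$statistic), p = wt$p.value,
             n = length(x) + length(y))
}

#' @param tab contingency table (matrix of counts).
#' @rdname stat-tests
#' @export
fisher_exact <- function(tab) {
  ft <- stats::fisher.test(tab)
  data.frame(statistic = NA_real_, p = ft$p.value, n = sum(tab))
}

#' @rdname stat-tests
#' @export
chi_square <- function(tab) {
  ct <- suppressWarnings(stats::chisq.test(tab))
  data.frame(statistic = unname(ct$statistic), p = ct$p.value, n = sum(tab))
}

#' Linear trend of an outcome across T classes
#'
#' Ordinary least squares of the outcome on the numeric T code (healthy T0
#' excluded: stage trends are a patients-only analysis). Reports the slope, its
#' t-based confidence interval, R-squared and the slope p-value; an outcome
#' with zero variance yields slope 0, R-squared 0 and a degenerate-flagged CI.
#'
#' @param outcome numeric outcome per session.
#' @param t_class integer T classes (0-4); T0 rows are dropped.
#' @param conf confidence level.
#' @return list: `slope`, `ci`, `r_squared`, `p`, `n`, `degenerate`.
#' @export
trend_regression <- function(outcome, t_class, conf = 0.95) {
  keep <- t_class >= 1 & !is.na(outcome)
  y <- outcome[keep]; t <- as.numeric(t_class[keep])
  if (length(unique(t)) < 3) stop("need at least 3 distinct T classes for a trend")
  if (stats::var(y) == 0)
    return(list(slope = 0, ci = c(0, 0), r_squared = 0, p = NA_real_,
                n = length(y), degenerate = TRUE))
  fit <- stats::lm(y ~ t)
  sm <- summary(fit)
  ci <- stats::confint(fit, "t", level = conf)
  list(slope = unname(stats::coef(fit)["t"]), ci = unname(ci[1, ]),
       r_squared = sm$r.squared, p = sm$coefficients["t", "Pr(>|t|)"],
       n = length(y), degenerate = FALSE)
}

#' Two-way ANOVA with type-III sums of squares
#'
#' Cell-means model with sum-to-zero contrasts and car's type-III tests, which
#' remain meaningful under the unbalanced designs a clinical cohort produces.
#' Empty factor-combination cells are an error naming the cell.
#'
#' @param outcome numeric outcome.
#' @param factor_a,factor_b factors (coerced).
#' @return data.frame: term, df, F, p.
#' @export
two_way_anova <- function(outcome, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("each factor needs at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: %s x %s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  dat <- data.frame(y = outcome, a = a, b = b)
  fit <- stats::lm(y ~ a * b, data = dat,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  terms3 <- c("factor_a", "factor_b", "interaction")
  df3 <- c(nlevels(a) - 1L, nlevels(b) - 1L, (nlevels(a) - 1L) * (nlevels(b) - 1L))
  # Deterministic (noise-free) designs have zero residual variance, which the
  # F ratio cannot express (0/0 for null terms, Inf for real ones). Resolve by
  # each term's own type-III sum of squares so the algebraic answer is
  # reported: dropping a term's columns from the sum-contrast model matrix
  # leaves a residual equal to that term's SS when the full fit is exact.
  tss <- sum((dat$y - mean(dat$y))^2)
  if (sum(stats::resid(fit)^2) < 1e-10 * max(tss, 1e-300)) {
    X <- stats::model.matrix(fit)
    asgn <- attr(X, "assign")
    ss <- vapply(1:3, function(k) {
      Xr <- X[, asgn != k, drop = FALSE]
      sum(stats::lsfit(Xr, dat$y, intercept = FALSE)$residuals^2)
    }, numeric(1))
    null_term <- ss < 1e-10 * max(tss, 1e-300)
    return(data.frame(term = terms3, df = df3,
                      F = ifelse(null_term, 0, Inf),
                      p = ifelse(null_term, 1, 0)))
  }
  an <- car::Anova(fit, type = 3)
  rows <- c("a", "b", "a:b")
  data.frame(term = terms3, df = an[rows, "Df"], F = an[rows, "F value"],
             p = an[rows, "Pr(>F)"], row.names = NULL)
}

#' Pre/post mixed-effects model with one clinical between-factor
#'
#' Fits a linear mixed model with a subject random intercept (REML), the
#' repeated-measures equivalent used by common GUI statistics packages when
#' post-op sessions can be missing. Reports Satterthwaite F-tests for time,
#' the clinical factor and their interaction, plus pairwise pre-vs-post
#' contrasts within each factor level, Sidak-corrected across levels
#' (uncorrected p also emitted). Factor levels contributed by a single subject
#' are excluded with a warning. With a single between-factor level and complete
#' data the time test reduces exactly to the paired t-test.
#'
#' @param data data.frame with the columns named below.
#' @param outcome,time,factor,subject column names (time must have levels
#'   "pre"/"post").
#' @return list: `tests` (term/F/df/p), `pairwise` (level, estimate, p,
#'   p_sidak), `fit` (the lmerMod), `excluded_levels`.
#' @export
mixed_prepost <- function(data, outcome = "FCR", time = "timepoint",
                          factor = "tclass", subject = "speaker") {
  d <- data.frame(y = data[[outcome]],
                  time = factor(data[[time]], levels = c("pre", "post")),
                  fct = factor(data[[factor]]),
                  subject = factor(data[[subject]]))
  d <- d[stats::complete.cases(d), ]
  n_subj <- tapply(d$subject, d$fct, function(s) length(unique(s)))
  excluded <- names(n_subj)[n_subj < 2]
  if (length(excluded) > 0) {
    warning("excluding factor level(s) with a single subject: ",
            paste(excluded, collapse = ", "))
    d <- droplevels(d[!(d$fct %in% excluded), ])
  }
  single_level <- nlevels(d$fct) < 2
  form <- if (single_level) y ~ time + (1 | subject) else y ~ time * fct + (1 | subject)
  fit <- lmerTest::lmer(form, data = d, REML = TRUE)
  an <- stats::anova(fit)  # lmerTest: type III, Satterthwaite df
  tests <- data.frame(term = rownames(an), df1 = an$NumDF, df2 = an$DenDF,
                      F = an$`F value`, p = an$`Pr(>F)`, row.names = NULL)
  tests$term[tests$term == "time"] <- "time"
  tests$term[tests$term == "fct"] <- "factor"
  tests$term[tests$term == "time:fct"] <- "time:factor"

  pairwise <- NULL
  if (!single_level) {
    emm <- emmeans::emmeans(fit, ~ time | fct, lmer.df = "satterthwaite")
    prs <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
    m <- nlevels(d$fct)
    pairwise <- data.frame(level = as.character(prs$fct),
                           estimate = prs$estimate, p = prs$p.value,
                           p_sidak = 1 - (1 - prs$p.value)^m)
  }
  list(tests = tests, pairwise = pairwise, fit = fit, excluded_levels = excluded)
}

#' Gender-balance tests of the cohort covariates
#'
#' Contingency tables of gender against each categorical covariate with
#' Fisher's exact test (the r x 2 generalization for multi-level covariates),
#' and a two-sample t-test for age.
#'
#' @param roster per-subject covariate table from [simulate_cohort()].
#' @return list: per covariate a list with `table` and `p`.
#' @export
balance_table <- function(roster) {
  pts <- roster[roster$role == "patient", ]
  out <- list()
  if ("age" %in% names(pts)) {
    tt <- t_test2(pts$age[pts$gender == "male"], pts$age[pts$gender == "female"])
    out$age <- list(table = NULL, p = tt$p)
  }
  for (v in c("tclass", "resection", "reconstruction", "flap")) {
    sub <- if (v == "flap") pts[pts$flap != "none", ] else pts
    tab <- table(sub[[v]], sub$gender)
    out[[v]] <- list(table = tab, p = fisher_exact(tab)$p)
  }
  out
}
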