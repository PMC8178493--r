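test_that("score_shi computes totals and subdomains", {
  expect_equal(score_shi(rep(0, 30)), list(total = 0, speech = 0, psychosocial = 0))
  expect_equal(score_shi(rep(4, 30))$speech, 56)
  expect_equal(score_shi(rep(4, 30))$psychosocial, 56)
  expect_equal(score_shi(rep(1, 30))$total, 30)

  # permutation within a domain leaves its score unchanged
  set.seed(1)
  items <- sample(0:4, 30, replace = TRUE)
  perm <- items
  perm[1:14] <- items[sample(1:14)]
  expect_equal(score_shi(perm)$speech, score_shi(items)$speech)

  expect_error(score_shi(rep(1, 29)), "30")
  expect_error(score_shi(c(rep(1, 29), 7)), "0")
})

test_that("cronbach_alpha matches hand arithmetic and limiting cases", {
  # two items over four subjects: alpha = 0.75 by hand
  fixture <- rbind(c(1, 2), c(2, 1), c(3, 4), c(4, 3))
  expect_equal(cronbach_alpha(fixture), 0.75)

  # perfectly correlated items
  base <- c(0, 1, 2, 3, 4)
  expect_equal(cronbach_alpha(cbind(base, base, base)), 1)

  # independent noise: alpha near 0
  set.seed(2)
  noise <- matrix(rnorm(1000 * 30), 1000, 30)
  expect_lt(abs(cronbach_alpha(noise)), 0.1)

  # shift invariance
  expect_equal(cronbach_alpha(fixture + 10), cronbach_alpha(fixture))

  expect_warning(a0 <- cronbach_alpha(rbind(c(1, 2), c(2, 1))), "variance")
  expect_true(is.na(a0))
  expect_error(cronbach_alpha(matrix(1:2, 1, 2)), "2")
})

test_that("shi_reliability scores all three domains", {
  m0 <- severity_model(shi_subject_sd = 0.3, shi_item_sd = 0.3)
  set.seed(3)
  fcrs <- runif(40, 0.9, 1.3)
  mat <- t(vapply(seq_along(fcrs), function(i) simulate_shi(fcrs[i], m0), integer(30)))
  al <- shi_reliability(mat)
  expect_named(al, c("total", "speech", "psychosocial"))
  expect_true(all(al > 0.8))
})

test_that("contingency tests match the published tables and full enumeration", {
  t1 <- matrix(c(18, 9, 2, 4), 2)
  t2 <- matrix(c(15, 8, 3, 1), 2)
  expect_equal(fisher_exact(t1)$p, 0.182, tolerance = 5e-3)
  expect_gt(fisher_exact(t2)$p, 0.999)
  expect_equal(fisher_exact(t1)$p, fisher_enumerate(t1), tolerance = 1e-9)
  expect_equal(fisher_exact(t2)$p, min(1, fisher_enumerate(t2)), tolerance = 1e-9)

  # enumeration oracle over random small tables
  set.seed(4)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    expect_equal(fisher_exact(tab)$p, min(1, fisher_enumerate(tab)),
                 tolerance = 1e-8)
  }

  expect_gt(chi_square(matrix(c(20, 20, 20, 20), 2))$p, 0.99)
})

test_that("rank and moment tests have the documented behavior", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.05)  # 1 / choose(6, 3)

  expect_true(is.na(pearson_test(rep(1, 5), rnorm(5))$statistic))
  expect_true(is.na(t_test2(rep(1, 5), rep(2, 5))$statistic))
  pt <- pearson_test(1:20, (1:20) * 2 + rnorm(20, sd = 1e-6))
  expect_gt(pt$statistic, 0.999)
  expect_lt(pt$p, 1e-10)
})

test_that("trend_regression fits the exact line and flags degenerates", {
  tr <- trend_regression(c(0.90, 0.95, 1.00, 1.05), c(1, 2, 3, 4))
  expect_equal(tr$slope, 0.05, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1, tolerance = 1e-9)

  # T0 rows are excluded from the fit
  tr0 <- trend_regression(c(5, 0.90, 0.95, 1.00, 1.05), c(0, 1, 2, 3, 4))
  expect_equal(tr0$slope, 0.05, tolerance = 1e-12)
  expect_equal(tr0$n, 4)

  flat <- trend_regression(rep(1, 8), rep(1:4, 2))
  expect_true(flat$degenerate)
  expect_equal(flat$slope, 0)

  expect_error(trend_regression(1:4, c(1, 1, 2, 2)), "3 distinct")
})

test_that("trend slope confidence interval has near-nominal coverage", {
  set.seed(5)
  cover <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    t <- sample(1:4, 400, replace = TRUE)
    y <- rnorm(400)
    tr <- trend_regression(y, t)
    if (tr$ci[1] <= 0 && 0 <= tr$ci[2]) cover <- cover + 1L
  }
  expect_gt(cover / n_rep, 0.91)
  expect_lt(cover / n_rep, 0.99)
})

test_that("two_way_anova resolves the deterministic additive design", {
  a <- rep(c("x", "y"), each = 10)
  b <- rep(rep(c("u", "v"), each = 5), 2)
  y <- ifelse(a == "x", 1, 3)  # effect on A only, zero noise
  an <- two_way_anova(y, a, b)
  expect_equal(an$p[an$term == "factor_a"], 0)
  expect_equal(an$p[an$term == "factor_b"], 1)
  expect_equal(an$p[an$term == "interaction"], 1)

  # planted interaction only
  set.seed(6)
  y2 <- rnorm(20, sd = 0.05) + ifelse(a == "x" & b == "u", 2, 0)
  an2 <- two_way_anova(y2, a, b)
  expect_lt(an2$p[an2$term == "interaction"], 1e-6)

  expect_error(two_way_anova(1:6, c("x", "x", "x", "y", "y", "y"),
                             c("u", "u", "u", "v", "v", "v")), "empty")
  expect_error(two_way_anova(1:6, rep("x", 6), rep(c("u", "v"), 3)), "levels")
})

test_that("mixed_prepost detects a planted level-specific post-op change", {
  set.seed(7)
  subj <- sprintf("s%02d", 1:24)
  lvl <- rep(c("T1", "T2", "T3", "T4"), each = 6)
  d <- expand.grid(speaker = subj, timepoint = c("pre", "post"),
                   stringsAsFactors = FALSE)
  d$tclass <- lvl[match(d$speaker, subj)]
  d$FCR <- 1 + rnorm(nrow(d), sd = 0.01) +
    ifelse(d$tclass == "T4" & d$timepoint == "post", 0.5, 0)
  res <- mixed_prepost(d)
  expect_lt(res$tests$p[res$tests$term == "time:factor"], 1e-6)
  sig <- res$pairwise$p_sidak < 0.05
  expect_true(sig[res$pairwise$level == "T4"])
  expect_false(any(sig[res$pairwise$level != "T4"]))
})

test_that("mixed_prepost reduces to the paired t-test in the degenerate case", {
  set.seed(8)
  subj <- sprintf("s%02d", 1:15)
  d <- expand.grid(speaker = subj, timepoint = c("pre", "post"),
                   stringsAsFactors = FALSE)
  d$tclass <- "T2"
  d$FCR <- 1 + rnorm(nrow(d), sd = 0.1) +
    ifelse(d$timepoint == "post", 0.07, 0)
  res <- mixed_prepost(d)
  pre <- d$FCR[d$timepoint == "pre"][order(d$speaker[d$timepoint == "pre"])]
  post <- d$FCR[d$timepoint == "post"][order(d$speaker[d$timepoint == "post"])]
  pt <- t.test(post, pre, paired = TRUE)
  # Satterthwaite df recovery is iterative, so agreement is to ~1e-5 relative
  expect_equal(res$tests$p[res$tests$term == "time"], pt$p.value, tolerance = 1e-4)
})

test_that("mixed_prepost excludes single-subject levels with a warning", {
  set.seed(9)
  subj <- sprintf("s%02d", 1:9)
  d <- expand.grid(speaker = subj, timepoint = c("pre", "post"),
                   stringsAsFactors = FALSE)
  d$tclass <- c(rep("T1", 4), rep("T2", 4), "T4")[match(d$speaker, subj)]
  d$FCR <- 1 + rnorm(nrow(d), sd = 0.1)
  expect_warning(res <- mixed_prepost(d), "T4")
  expect_identical(res$excluded_levels, "T4")
  expect_false("T4" %in% res$pairwise$level)
})

test_that("balance_table reproduces the published contingency p-values", {
  cohort <- simulate_cohort(cohort_config("validation", seed = 1))
  bal <- balance_table(cohort$roster)
  expect_equal(bal$reconstruction$p, 0.182, tolerance = 5e-3)
  expect_gt(bal$flap$p, 0.999)
  expect_true(is.numeric(bal$age$p))
  expect_true(all(c("tclass", "resection") %in% names(bal)))
})
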