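test_that("a planted single-feature rule is recovered with negative weight", {
  d <- planted_fcr_data(n = 200, seed = 42)
  m <- train_syllable_model(d$x, d$y, seed = 1)
  w <- m$weights
  expect_equal(names(which.max(abs(w))), "FCR")
  expect_lt(w["FCR"], 0)
  expect_gte(m$cv$accuracy, 0.95)
  expect_lte(m$n_sv, nrow(d$x))
})

test_that("separable toy sets and degenerate labels behave as documented", {
  x <- matrix(0, 4, 15, dimnames = list(NULL, feature_names()))
  x[, "FCR"] <- c(0.8, 0.85, 1.2, 1.25)
  y <- c(1, 1, 0, 0)
  expect_warning(m <- train_syllable_model(x, y, folds = 10, seed = 1), "folds")
  expect_equal(m$cv$accuracy, 1.0)
  expect_gte(m$n_sv, 2)

  expect_error(train_syllable_model(x, rep(1, 4)), "degenerate")
  expect_error(train_syllable_model(x, c(2, 1, 0, 0)), "0/1")
})

test_that("training is deterministic and the decision function is consistent", {
  d <- planted_fcr_data(n = 120, seed = 7)
  m1 <- train_syllable_model(d$x, d$y, seed = 3)
  m2 <- train_syllable_model(d$x, d$y, seed = 3)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-8)
  expect_equal(m1$cv$accuracy, m2$cv$accuracy)

  # sign(standardized x . w + b) reproduces in-sample predictions
  xs <- scale(d$x, center = m1$center, scale = m1$scale)
  score <- drop(xs %*% m1$weights) + m1$bias
  self <- evaluate_model(m1, d$x, d$y)
  expect_equal(self$accuracy, mean((score > 0) == (d$y == 1)))
  expect_gte(self$accuracy, 0.95)
})

test_that("evaluate_model reports honest metrics and missing ratios", {
  d <- planted_fcr_data(n = 1000, seed = 10)
  m <- train_syllable_model(d$x[1:200, ], d$y[1:200], seed = 1)

  # permuted labels: no signal, AUC near 1/2
  set.seed(4)
  yp <- sample(d$y)
  expect_lt(abs(evaluate_model(m, d$x, yp)$auc - 0.5), 0.05)

  # all-negative test labels: sensitivity undefined, specificity defined
  met <- evaluate_model(m, d$x[d$y == 0, ], d$y[d$y == 0])
  expect_true(is.na(met$sensitivity))
  expect_false(is.na(met$specificity))

  xbad <- d$x
  colnames(xbad)[1] <- "XX"
  expect_error(evaluate_model(m, xbad, d$y), "feature")
})

test_that("lpc_matrix assembles 15 x 12 and names missing syllables", {
  corp <- syllable_corpus()
  models <- lapply(seq_len(12), function(i) {
    d <- planted_fcr_data(n = 60, seed = i)
    train_syllable_model(d$x, d$y, folds = 0, seed = 1, syllable = corp$syllable[i])
  })
  names(models) <- corp$syllable
  mat <- lpc_matrix(models)
  expect_equal(dim(mat), c(15L, 12L))
  expect_identical(rownames(mat), feature_names())
  expect_equal(mat[, "da"], models[["da"]]$weights)

  expect_error(lpc_matrix(models[-3]), corp$syllable[3])
})

test_that("rank_predictors ranks by mean absolute weight with canonical ties", {
  mat <- matrix(runif(15 * 12, -0.1, 0.1), 15, 12,
                dimnames = list(feature_names(), NULL))
  mat["FCR", ] <- -3
  rk <- rank_predictors(mat)
  expect_equal(rk$dominant, "FCR")
  expect_false(rk$degenerate)
  expect_true(rk$ranking$all_negative[rk$ranking$feature == "FCR"])
  expect_equal(rk$ranking$rank, 1:15)

  zero <- matrix(0, 15, 12, dimnames = list(feature_names(), NULL))
  rz <- rank_predictors(zero)
  expect_true(rz$degenerate)
  expect_identical(rz$ranking$feature, feature_names())
})

test_that("gender comparison of weights detects planted shifts", {
  set.seed(8)
  male <- matrix(rnorm(15 * 12), 15, 12, dimnames = list(feature_names(), NULL))
  female <- matrix(rnorm(15 * 12), 15, 12, dimnames = list(feature_names(), NULL))
  cmp0 <- compare_lpc_across_gender(male, male)
  expect_true(all(cmp0$p == 1, na.rm = TRUE))
  expect_true(all(cmp0$t == 0, na.rm = TRUE))

  shifted <- male
  shifted["VSA", ] <- female["VSA", ] + 10 * sd(female["VSA", ])
  cmp <- compare_lpc_across_gender(shifted, female)
  expect_lt(cmp$p[cmp$feature == "VSA"], 0.001)
  expect_true("p_holm" %in% names(cmp))

  # constant rows in both genders: undefined, reported missing
  cm <- male; cf <- female
  cm["GA_U", ] <- 1; cf["GA_U", ] <- 1
  cmpc <- compare_lpc_across_gender(cm, cf)
  expect_true(is.na(cmpc$p[cmpc$feature == "GA_U"]))

  expect_error(compare_lpc_across_gender(male, female[, 1:6]), "shape")
})

test_that("screen_markers runs the full stage on a default screening cohort", {
  # at the default size every syllable x gender cell sees both outcome
  # classes; much smaller cohorts can hit the documented degenerate-syllable
  # error in train_syllable_model
  cohort <- simulate_cohort(cohort_config("screening", seed = 3))
  res <- screen_markers(cohort$sessions, cohort$perception, folds = 0, seed = 1)
  expect_equal(dim(res$lpc$male), c(15L, 12L))
  expect_equal(dim(res$lpc$female), c(15L, 12L))
  expect_s3_class(res$gender_comparison, "data.frame")
  expect_true(res$ranking$dominant %in% feature_names())
})
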