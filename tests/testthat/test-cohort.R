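test_that("severity_model validates its parameters", {
  expect_s3_class(severity_model(), "severity_model")
  expect_error(severity_model(lambda_t = c(T0 = 0, T1 = 0.2, T2 = 0.1,
                                           T3 = 0.3, T4 = 0.4)), "non-decreasing")
  expect_error(severity_model(b1 = -2), "non-negative")
})

test_that("the logistic link behaves as configured", {
  m <- severity_model()
  # degenerate slope: probability independent of fcr
  m0 <- severity_model(b1 = 0)
  expect_equal(p_deviated(0.8, "alveolar", m0), p_deviated(1.4, "alveolar", m0))
  expect_equal(p_deviated(1.0, "alveolar", m0), plogis(m0$b0))
  # logistic limit
  expect_gt(p_deviated(10, "alveolar", m), 0.999)
  # monotone in fcr, ordered by place offset
  expect_gt(p_deviated(1.1, "alveolar", m), p_deviated(0.9, "alveolar", m))
  expect_gt(p_deviated(1, "alveolo-palatal", m), p_deviated(1, "velar", m))
  expect_error(p_deviated(1, "labial", m), "place")
})

test_that("empirical deviation rate matches the logistic closed form", {
  m <- severity_model()
  fcr <- 1.02
  n <- 10000
  set.seed(11)
  draws <- replicate(n / 12, simulate_perception(fcr, m)$outcome)
  for (pl in c("alveolar", "alveolo-palatal", "velar")) {
    corp <- syllable_corpus()
    idx <- which(corp$place == pl)
    p_hat <- 1 - mean(draws[idx, ])
    p_true <- p_deviated(fcr, pl, m)
    se <- sqrt(p_true * (1 - p_true) / (length(idx) * ncol(draws)))
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-9)
  }
})

test_that("questionnaire simulation follows its latent link", {
  # zero noise: identical fcr implies identical items, alpha = 1 across fcrs
  m0 <- severity_model(shi_subject_sd = 0, shi_item_sd = 0)
  a <- simulate_shi(1.0, m0, seed = 1)
  b <- simulate_shi(1.0, m0, seed = 99)
  expect_identical(a, b)
  fcrs <- seq(0.85, 1.25, length.out = 20)
  items0 <- t(vapply(fcrs, function(f) simulate_shi(f, m0, seed = 5), integer(30)))
  expect_equal(cronbach_alpha(items0), 1)

  # zero slope: FCR carries no information about the total. The intercept is
  # raised to mid-scale so the items are not all clipped to 0 (which would
  # make the correlation 0/0 rather than null).
  mflat <- severity_model(shi_slope = 0, shi_intercept = 2)
  set.seed(21)
  fcrs <- runif(1000, 0.85, 1.25)
  totals <- vapply(seq_along(fcrs),
                   function(i) sum(simulate_shi(fcrs[i], mflat)), numeric(1))
  expect_lt(abs(cor(fcrs, totals)), 3 / sqrt(1000) + 0.02)

  # default calibration: strong positive correlation at n = 33
  m <- severity_model()
  hits <- 0L
  for (r in 1:50) {
    set.seed(r)
    fcrs <- runif(33, 0.9, 1.3)
    totals <- vapply(seq_along(fcrs),
                     function(i) sum(simulate_shi(fcrs[i], m)), numeric(1))
    if (cor(fcrs, totals) >= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 45)
})

test_that("the default validation cohort reproduces the published bookkeeping", {
  cohort <- simulate_cohort(cohort_config("validation", seed = 1))
  expect_equal(nrow(cohort$sessions), 65)
  expect_equal(followup_rate(cohort), 97)
  # 33 patients, 20 male / 13 female
  expect_equal(sum(cohort$roster$role == "patient"), 33)
  expect_equal(sum(cohort$roster$gender == "male" & cohort$roster$role == "patient"), 20)
  # the single dropout is the last enrolled (male) patient
  pre_only <- setdiff(cohort$sessions$speaker[cohort$sessions$timepoint == "pre"],
                      cohort$sessions$speaker[cohort$sessions$timepoint == "post"])
  expect_length(pre_only, 1)
  expect_equal(cohort$roster$gender[cohort$roster$speaker == pre_only], "male")
  # bundled outcomes: 12 syllables and 30 items per session
  expect_equal(nrow(cohort$perception), 65 * 12)
  expect_equal(dim(cohort$shi), c(65L, 30L))
})

test_that("cohort edge cases behave as documented", {
  two <- simulate_cohort(cohort_config("validation", n_patients = 1,
                                       male_patients = 1,
                                       recon_male = 1, alt_male = 1,
                                       dropout = 0, seed = 2))
  expect_equal(nrow(two$sessions), 2)
  expect_error(cohort_config("validation", n_patients = 3, dropout = 3), "dropout")
  expect_error(cohort_config("validation", n_patients = 0), "n_patients")
})

test_that("cohort generation is deterministic given the seed", {
  cfg <- cohort_config("validation", seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$shi, b$shi)
  expect_identical(a$perception, b$perception)
  c2 <- simulate_cohort(cohort_config("validation", seed = 78))
  expect_false(identical(a$sessions$FCR, c2$sessions$FCR))
})

test_that("mean FCR is non-decreasing in T class under the default model", {
  ok <- 0L
  for (r in 1:20) {
    cohort <- simulate_cohort(cohort_config("screening", seed = r))
    pre <- cohort$sessions[cohort$sessions$timepoint == "pre" &
                             cohort$sessions$tclass >= 1, ]
    mu <- tapply(pre$FCR, pre$tclass, mean)
    if (all(diff(mu) > -1e-9)) ok <- ok + 1L
  }
  expect_gte(ok, 18)
})

test_that("the audio observation path synthesizes, writes and re-extracts", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(
    cohort_config("validation", n_patients = 2, male_patients = 1,
                  recon_male = 1, recon_female = 1, alt_male = 1, alt_female = 1,
                  dropout = 0, observation = "audio", seed = 5),
    audio_dir = dir)
  expect_equal(nrow(cohort$sessions), 4)
  wavs <- list.files(dir, pattern = "\\.wav$")
  expect_length(wavs, 4 * 3)
  expect_true(all(grepl("^P[0-9]+_(pre|post)_[AIU]\\.wav$", wavs)))
  # extraction-based features agree with the generated truth
  expect_lt(max(abs(cohort$sessions$FCR - cohort$sessions$fcr_true)), 0.1)
  clip <- read_wav(file.path(dir, wavs[1]))
  expect_equal(clip$rate, 44100)
})
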