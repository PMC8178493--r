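test_that("find_steady_segment honors the earliest-start tie-break", {
  # constant-amplitude tone whose period (551 samples) equals the 12.5-ms
  # subframe hop: every subframe is sample-identical, so every admissible
  # window has exactly the same stability cost and the tie-break must fire
  x <- 0.5 * sin(2 * pi * (0:44099) / 551)
  seg <- find_steady_segment(audio_clip(x, 44100))
  expect_lt(seg$start, 0.02)
  expect_equal(seg$duration, 0.2)
  expect_length(seg$samples, round(0.2 * 44100))
})

test_that("find_steady_segment stays inside the voiced region", {
  # 300-ms vowel centered in 1 s of (near) silence
  tg <- formant_targets("male")
  voiced <- synthesize_vowel("A", tg, duration = 0.3, seed = 2)$samples
  x <- numeric(44100)
  start <- round(0.35 * 44100)
  x[start + seq_along(voiced)] <- voiced
  seg <- find_steady_segment(audio_clip(x, 44100))
  expect_gte(seg$start, 0.35 - 1e-9)
  expect_lte(seg$start + seg$duration, 0.65 + 1e-2)
})

test_that("find_steady_segment rejects short or silent clips", {
  expect_error(find_steady_segment(audio_clip(sin(1:4410 / 5), 44100)), "shorter")
  expect_error(find_steady_segment(audio_clip(numeric(44100), 44100)), "silence")
})

test_that("lp estimates recover synthesis truth within +/- 40 Hz", {
  for (g in c("male", "female")) {
    tg <- formant_targets(g)
    f0 <- if (g == "male") 120 else 200
    for (v in c("A", "I", "U")) {
      clip <- synthesize_vowel(v, tg, f0 = f0, seed = 7)
      est <- estimate_formants(find_steady_segment(clip), "lp", g)
      expect_lt(abs(est$F1 - tg$freq[v, "F1"]), 40)
      expect_lt(abs(est$F2 - tg$freq[v, "F2"]), 40)
      expect_gte(est$quality, 0.9)
    }
  }
})

test_that("lp and fft512 agree on the reference /i/ segment", {
  # the documented cross-method case: /i/ with F1 = 270, F2 = 2290 under the
  # female ceiling; agreement within one 512-point FFT bin at 44.1 kHz (86 Hz)
  tg <- formant_targets("female",
                        values = rbind(A = c(850, 1220), I = c(270, 2290), U = c(370, 950)))
  for (f0 in c(120, 200)) {
    seg <- find_steady_segment(synthesize_vowel("I", tg, f0 = f0, seed = 7))
    lp <- estimate_formants(seg, "lp", "female")
    ff <- estimate_formants(seg, "fft512", "female")
    expect_lt(abs(lp$F1 - ff$F1), 86)
    expect_lt(abs(lp$F2 - ff$F2), 86)
    expect_equal(ff$method, "fft512")
    expect_true(ff$quality >= 0 && ff$quality <= 1)
  }
})

test_that("white noise yields low quality or an estimation error", {
  for (seed in 1:3) {
    set.seed(seed)
    seg <- find_steady_segment(audio_clip(runif(44100, -0.5, 0.5), 44100))
    q <- tryCatch(estimate_formants(seg, "lp", "male")$quality, error = function(e) 0)
    expect_lt(q, 0.5)
  }
})

test_that("estimate_formants validates inputs and aggregation", {
  tg <- formant_targets("male")
  seg <- find_steady_segment(synthesize_vowel("I", tg, seed = 1))
  expect_error(estimate_formants(list(samples = 1:10), "lp", "male"))
  est <- estimate_formants(seg, "lp", "male")
  expect_lt(est$F1, est$F2)
  expect_identical(est$method, "lp")
})

test_that("extract_profile aggregates repetitions and names failing vowels", {
  tg <- formant_targets("male")
  clips <- list(
    A = lapply(1:3, function(s) synthesize_vowel("A", tg, seed = s)),
    I = synthesize_vowel("I", tg, seed = 4),
    U = synthesize_vowel("U", tg, seed = 5)
  )
  prof <- extract_profile(clips, "S1", "male", "pre")
  expect_s3_class(prof, "formant_profile")
  expect_true(all(abs(prof$freq - tg$freq) < 40))

  expect_error(extract_profile(clips[c("A", "I")], "S1", "male"), "U")

  clips$U <- audio_clip(numeric(44100), 44100)  # silent clip cannot be framed
  expect_error(extract_profile(clips, "S1", "male"), "vowel U")
})

test_that("formant_profile enforces its invariants", {
  expect_error(formant_profile("s", "male", "pre",
                               rbind(A = c(1090, 730), I = c(270, 2290), U = c(300, 870))),
               "F1 < F2")
  expect_error(formant_profile("s", "male", "pre",
                               rbind(A = c(NA, 1090), I = c(270, 2290), U = c(300, 870))))
})
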