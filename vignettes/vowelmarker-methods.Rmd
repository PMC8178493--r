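---
title: "Methods: generator, estimators and statistical pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generator, estimators and statistical pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the numerical decisions behind
`vowelmarker`: what the synthetic cohort generator assumes, what every default
parameter means, and why the formant estimators are built the way they are.

## 1. Why the formant centralization ratio

The corner vowels /ɑ/, /i/ and /u/ span the articulatory working space of the
tongue. Disease or resection of the tongue body limits those excursions, so
the measured first and second formants of the three vowels drift toward their
common centroid. Three families of acoustic summaries are in common use:

* absolute formants (F1, F2 per vowel) and their per-vowel contrasts
  `CD(v) = F2(v) − F1(v)` and gravity centers `GA(v) = (F1(v) + F2(v))/2`;
* the vowel space area `VSA`, the area of the triangle the three vowels span
  in the (F1, F2) plane, and its logarithm `JoosVSA = log10(VSA)`;
* the formant centralization ratio
  `FCR = (F2u + F2ɑ + F1i + F1u) / (F2i + F1ɑ)`.

FCR rises monotonically under centralization and reaches exactly 2 when the
three vowels coincide (substitute equal formants into the ratio). Its key
property is scale invariance: all six formants scale with vocal-tract length,
which varies on the order of 10% between same-gender adults, and the ratio
cancels that factor while VSA scales with its square. The screening stage of
this package is precisely an empirical demonstration that, once realistic
anatomical variation is present, a linear classifier finds FCR — and not VSA
or any raw formant — to be the reliable predictor of perceptual outcomes.

## 2. The synthetic cohort generator

`simulate_cohort(cohort_config(...))` draws a roster of patients (plus
optional healthy controls) and produces one session per subject and
timepoint. The causal chain, parameterized by `severity_model()`, is:

1. **Severity to centralization.** Each subject's clinical T class maps to a
   centralization weight λ: `lambda_t = (0, .05, .12, .22, .32)` for T0–T4
   pre-operatively; a post-operative session adds `lambda_surg` by resection
   extent (partial glossectomy .08, hemiglossectomy .15, subtotal/total .30).
   A per-subject normal deviation (`lambda_sd = .04`) spreads severity within
   class. λ is clipped to [0, 1]; `centralize()` moves every formant a
   fraction λ toward the F1/F2 centroid of the gender's target triangle.
   These weights are calibrated to sign and ordering only (monotone trend,
   larger resections worse, post worse than pre), not to any quantitative
   effect size.
2. **Speaker anatomy.** All six formants are multiplied by a per-subject
   vocal-tract scale factor, `N(1, speaker_scale_sd = 0.12)`, and by
   per-formant idiolectal factors `exp(N(0, vowel_shape_sd = 0.08))` that
   model vowel-quality differences between speakers. Session-level additive
   jitter (`formant_jitter_sd = 15` Hz) models articulatory variability
   between takes. The produced formants define the session's true FCR.
3. **Observation.** In the `parametric` path the measured formants are the
   produced ones plus `measurement_sd = 5` Hz of noise. In the `audio` path
   each vowel is synthesized as 1 s of 44.1 kHz PCM audio, written as WAV,
   and re-measured with the package's own extractor; this is slower but
   exercises the full signal chain (round-trip FCR error ≤ 0.024 in the
   shipped demonstration).
4. **Perception.** Each of 12 consonant-vowel syllables (3 place groups:
   alveolar, alveolo-palatal, velar) receives a Bernoulli outcome with
   `P(deviated) = plogis(b0 + b1 (FCR − center) + place offset)`, with
   `b0 = −1.2`, `b1 = 28`, `center = 1.0`, offsets (0, +0.8, −0.4). The
   alveolo-palatal offset makes that group most error-prone. `b1` is
   calibrated so the per-syllable SVMs reach cross-validated AUCs around
   0.85–0.95 — with single-draw binary labels a much weaker link leaves the
   classifiers unable to pin down even the sign of the feature weights, which
   no finite study design would tolerate at the screening stage.
5. **Questionnaire.** A latent severity `−6.4 + 8·FCR + N(0, 0.3)` generates
   30 items (0–4 scale, item noise SD 0.5, clipped); items 1–14 and 15–28
   form the speech and psychosocial subdomains. A shared latent per session
   produces the high internal consistency (α > 0.98) that questionnaire
   validation expects.

Cohort margins mirror a realistic surgical series: 33 validation patients
(20 male / 13 female) with reconstruction 18/2 vs 9/4 by gender (Fisher
p = 0.182) and ALT flaps 15/3 vs 8/1 (p > 0.999), one male post-operative
dropout (65 sessions, 97% follow-up); the screening role generates 156
pre-operative sessions from 80 male and 76 female speakers. These sizes are
the package's own defaults and every one of them is a `cohort_config`
argument.

**Realism limits.** The generator is a calibration and testing instrument,
not a speech model: consonant audio is never synthesized (syllable outcomes
are labels), severity acts only through vowel centralization, all noise is
Gaussian, ages are balanced in expectation only (any single draw can show a
chance imbalance), and post-operative change is purely additive with no
recovery dynamics.

## 3. Formant estimation

`find_steady_segment` scans 200-ms windows on a 12.5-ms grid and keeps the
window minimizing the variance of short-time log-energy plus the variance of
the spectral centroid (in kHz) over 25-ms subframes, among windows whose every
subframe RMS reaches 10% of the clip's peak subframe RMS; cost ties go to the
earliest start.

`estimate_formants` supports two dialects, both operating on the segment
downsampled to twice a gender-specific ceiling (5000 Hz male, 5500 Hz female)
and pre-emphasized (coefficient 0.97):

* **`lp` (default).** Covariance-method linear prediction of order
  `2 + fs/1000` per subframe, refit after discarding rows whose prediction
  residuals exceed `median + 4·MAD` (up to 3 passes). The trimming removes
  glottal-pulse instants — the cause of harmonic locking at high f0 — while
  leaving noise-like frames essentially untrimmed, so unvoiced input is not
  over-fitted into spurious resonances and instead yields a low quality
  score. Candidates are polynomial roots with bandwidth < 400 Hz, modulus
  > 0.7 and frequency inside (90, 0.95·ceiling); per-subframe (F1, F2) pairs
  are aggregated by the median, and `quality` is the fraction of subframes
  with two admissible candidates. A fixed trimming fraction was rejected
  because it over-fits white noise into narrow fake resonances; the
  MAD-threshold version leaves the estimator's 14-Hz worst-case error on the
  synthesis grid intact while keeping noise quality scores below 0.5.
* **`fft512`.** Per subframe, a 512-point power spectrum is smoothed by a
  moving average of exactly one harmonic spacing (the cepstrum of the whole
  segment supplies f0); an average over one period has a spectral null at the
  harmonic ripple frequency, so the envelope survives while the harmonics
  cancel. Peaks need 2 dB of saddle prominence and are refined by parabolic
  interpolation; aggregation is the same median over subframes. This dialect
  matches `lp` within tens of Hz for well-separated formants but merges
  F1/F2 pairs closer than about one harmonic spacing at high f0 (/ɑ/-type
  vowels), which is why `lp` is the default.

## 4. Screening and validation statistics

* Per-syllable, per-gender soft-margin linear SVMs (`e1071`, C = 1) on
  z-scored features; weight orientation is fixed so the positive class is a
  correct articulation, hence centralization-tracking features get negative
  weights. Markers are ranked by mean |weight| across the 24 models (absolute
  value so sign conventions cannot cancel), with ties broken by canonical
  feature order.
* Gender dimorphism of weights: per-feature two-sample t-tests across the 12
  syllable weights, uncorrected (plus a Holm column); zero-variance rows are
  reported as missing.
* Validation: Cronbach's α for SHI domains; Pearson correlation FCR–SHI;
  least-squares stage trend over T1–T4 (controls excluded from the slope);
  type-III two-way ANOVA (sum contrasts) with an exact algebraic branch for
  zero-residual designs; a subject-random-intercept mixed model for pre/post
  with Satterthwaite tests and Sidak-corrected per-stage contrasts — with one
  stage and complete data it reduces to the paired t-test to ~1e−5 relative
  accuracy.
* Diagnostics: a hand-written ROC whose trapezoid AUC equals the tie-aware
  pair-counting estimator to 1e−12, Hanley–McNeil (default) or DeLong
  standard errors, and Youden-optimal cutoffs placed at score midpoints with
  ties resolved toward higher specificity.

## 5. Limitations

Every quantitative default above is a generator choice, not an empirical
claim; the pipeline's value is that its statistical machinery is validated
against oracles (closed-form links, enumeration, brute-force pair counting,
planted-rule recovery) so it can be pointed at real recordings unchanged. The
synthesis covers sustained vowels only, and the `fft512` estimator is
provided for comparability, not as the recommended method.
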