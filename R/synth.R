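#' Corner-vowel formant targets
#'
#' Default F1/F2 targets for the three corner vowels /a/, /i/, /u/, per gender.
#' The defaults are classic adult values from the acoustic-phonetics literature;
#' they are editable generator inputs, not measurements of any particular
#' cohort. Bandwidth defaults are B1 = 80 Hz, B2 = 120 Hz for all vowels.
#'
#' @param gender "male" or "female".
#' @param values optional 3x2 matrix (rows A, I, U; columns F1, F2) overriding
#'   the defaults.
#' @param b1,b2 formant bandwidths in Hz.
#' @return an object of class `formant_targets`: list with `gender`, `freq`
#'   (3x2 matrix, rows "A","I","U", cols "F1","F2") and `bw` (length-2).
#' @export
formant_targets <- function(gender = c("male", "female"), values = NULL,
                            b1 = 80, b2 = 120) {
  gender <- match.arg(gender)
  if (is.null(values)) {
    values <- if (gender == "male") {
      rbind(A = c(730, 1090), I = c(270, 2290), U = c(300, 870))
    } else {
      rbind(A = c(850, 1220), I = c(310, 2790), U = c(370, 950))
    }
  }
  values <- as.matrix(values)
  stopifnot(nrow(values) == 3, ncol(values) == 2)
  rownames(values) <- c("A", "I", "U")
  colnames(values) <- c("F1", "F2")
  if (any(values <= 0)) stop("formant targets must be positive")
  if (any(values[, "F2"] <= values[, "F1"])) stop("F2 must exceed F1 for every vowel")
  if (values["I", "F2"] <= values["U", "F2"]) stop("front vowel /i/ must have F2 above back vowel /u/")
  structure(list(gender = gender, freq = values, bw = c(B1 = b1, B2 = b2)),
            class = "formant_targets")
}

#' Centralize formant targets toward the vowel-space centroid
#'
#' Moves each vowel's F1 and F2 a fraction `lambda` of the way toward the
#' centroid of the three corner vowels (computed separately for F1 and F2).
#' `lambda = 0` is the identity; at `lambda = 1` the vowel triangle collapses to
#' a point, where the formant centralization ratio equals exactly 2 and the
#' vowel space area is 0.
#'
#' @param targets a `formant_targets` object.
#' @param lambda centralization fraction in \eqn{[0, 1]}.
#' @return a `formant_targets` object with interpolated frequencies.
#' @export
centralize <- function(targets, lambda) {
  stopifnot(inherits(targets, "formant_targets"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  centroid <- colMeans(targets$freq)
  freq <- (1 - lambda) * targets$freq +
    lambda * matrix(centroid, nrow = 3, ncol = 2, byrow = TRUE)
  out <- targets
  out$freq <- freq
  out
}

# Klatt-style digital resonator applied in cascade: poles at radius
# exp(-pi*B/rate) and angle 2*pi*F/rate, unity gain at DC.
resonator_filter <- function(x, f, b, rate) {
  r <- exp(-pi * b / rate)
  theta <- 2 * pi * f / rate
  B <- 2 * r * cos(theta)
  C <- -r^2
  A <- 1 - B - C
  as.numeric(stats::filter(A * x, filter = c(B, C), method = "recursive"))
}

#' Synthesize a sustained corner vowel
#'
#' Source-filter synthesis: a glottal pulse train at `f0` (with a gentle 3%
#' vibrato at 5 Hz, as in natural sustained phonation) is shaped by a one-pole
#' glottal tilt filter and passed through a cascade of second-order resonators
#' at the target (F1, B1) and (F2, B2) plus two fixed higher resonators
#' (F3/F4 defaults 2,900/3,900 Hz male and 3,300/4,300 Hz female), with
#' additive Gaussian noise. The synthesis parameters are the ground truth
#' against which formant extraction is validated.
#'
#' @param vowel one of "A", "I", "U".
#' @param targets a `formant_targets` object.
#' @param f0 fundamental frequency in Hz.
#' @param duration duration in seconds (>= 0.25 s so a 200-ms analysis frame fits).
#' @param rate sampling rate in Hz; must exceed twice the highest resonator.
#' @param noise_level additive noise standard deviation relative to the RMS of
#'   the clean signal (0.01 is roughly 40 dB SNR).
#' @param seed integer seed; synthesis is bit-reproducible given the seed.
#' @param vibrato_depth,vibrato_rate fractional f0 modulation depth and rate (Hz).
#' @param tilt glottal spectral-tilt pole (0 disables the source filter).
#' @return an `audio_clip` normalized to peak 0.9.
#' @export
synthesize_vowel <- function(vowel, targets, f0 = 120, duration = 1,
                             rate = 44100, noise_level = 0.01, seed = 1L,
                             vibrato_depth = 0.03, vibrato_rate = 5,
                             tilt = 0.99) {
  stopifnot(inherits(targets, "formant_targets"))
  vowel <- match.arg(vowel, c("A", "I", "U"))
  if (f0 <= 0) stop("f0 must be positive")
  if (duration < 0.25) stop("duration must be at least 0.25 s to host a 200-ms analysis frame")
  f1 <- targets$freq[vowel, "F1"]
  f2 <- targets$freq[vowel, "F2"]
  high <- if (targets$gender == "female") c(3300, 4300) else c(2900, 3900)
  if (rate < 2 * max(f2, high)) stop("sampling rate below Nyquist limit for the requested formants")

  n <- round(duration * rate)
  tt <- (0:(n - 1)) / rate
  f0_t <- f0 * (1 + vibrato_depth * sin(2 * pi * vibrato_rate * tt))
  phase <- cumsum(f0_t) / rate
  src <- numeric(n)
  src[c(1L, which(diff(floor(phase)) == 1) + 1L)] <- 1
  y <- if (tilt > 0) as.numeric(stats::filter(src, tilt, method = "recursive")) else src
  for (spec in list(c(f1, targets$bw["B1"]), c(f2, targets$bw["B2"]),
                    c(high[1], 200), c(high[2], 250))) {
    y <- resonator_filter(y, spec[1], spec[2], rate)
  }
  if (noise_level > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(n, sd = noise_level * stats::sd(y))
  }
  y <- 0.9 * y / max(abs(y))
  audio_clip(y, rate)
}
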