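#' Formant profile of one recording session
#'
#' Bundles one F1/F2 measurement per corner vowel for a single speaker and
#' timepoint. The constructor enforces exactly three vowels (A, I, U) with
#' 0 < F1 < F2 each.
#'
#' @param speaker speaker identifier.
#' @param gender "male" or "female".
#' @param timepoint "pre" or "post".
#' @param freq 3x2 numeric matrix, rows "A","I","U", columns "F1","F2" (Hz).
#' @param quality per-vowel quality scores in \eqn{[0,1]} (default 1).
#' @param method estimation method tag.
#' @return an object of class `formant_profile`.
#' @export
formant_profile <- function(speaker, gender, timepoint, freq,
                            quality = c(A = 1, I = 1, U = 1), method = "direct") {
  freq <- as.matrix(freq)
  stopifnot(nrow(freq) == 3, ncol(freq) == 2)
  rownames(freq) <- c("A", "I", "U")
  colnames(freq) <- c("F1", "F2")
  if (any(!is.finite(freq)) || any(freq <= 0)) stop("formants must be positive and finite")
  if (any(freq[, "F2"] <= freq[, "F1"])) stop("each vowel must have F1 < F2")
  structure(list(speaker = speaker, gender = gender, timepoint = timepoint,
                 freq = freq, quality = quality, method = method),
            class = "formant_profile")
}

#' @export
print.formant_profile <- function(x, ...) {
  cat(sprintf("<formant_profile: %s/%s/%s (%s)>\n",
              x$speaker, x$gender, x$timepoint, x$method))
  print(round(x$freq, 1))
  invisible(x)
}

# Per-subframe short-time features used both for steady-segment selection and
# as the framing grid for formant estimation.
subframe_grid <- function(n, rate, sub = 0.025, hop = 0.0125) {
  sub_n <- round(sub * rate)
  hop_n <- round(hop * rate)
  starts <- seq(1L, n - sub_n + 1L, by = hop_n)
  list(starts = starts, sub_n = sub_n, hop_n = hop_n)
}

#' Locate the steadiest analysis segment of a sustained vowel
#'
#' Scans frame-length windows on a 12.5-ms grid and returns the window
#' minimizing a stability cost: the variance of short-time log-energy plus the
#' variance of the spectral centroid (in kHz) across 25-ms subframes. Only
#' windows whose every subframe RMS reaches at least 10% of the clip's peak
#' subframe RMS are admissible, so leading/trailing silence is never selected.
#' Cost ties are broken toward the earliest start.
#'
#' @param clip an `audio_clip`.
#' @param frame analysis frame length in seconds (default 0.200).
#' @return a `steady_segment`: list with `start` (s), `duration` (s),
#'   `samples`, `rate`.
#' @export
find_steady_segment <- function(clip, frame = 0.200) {
  stopifnot(inherits(clip, "audio_clip"))
  n <- length(clip$samples)
  if (n < round(frame * clip$rate)) stop("clip shorter than the analysis frame")
  g <- subframe_grid(n, clip$rate)
  x <- clip$samples
  nfft <- 2048L
  freqs <- (0:(nfft / 2 - 1)) * clip$rate / nfft
  feats <- vapply(g$starts, function(s) {
    seg <- x[s:(s + g$sub_n - 1L)]
    rms <- sqrt(mean(seg^2))
    mag <- Mod(stats::fft(c(seg * signal::hamming(g$sub_n),
                            numeric(nfft - g$sub_n))))[1:(nfft / 2)]
    cent <- if (sum(mag) > 0) sum(freqs * mag) / sum(mag) else 0
    c(rms = rms, loge = log(rms^2 + 1e-12), cent_khz = cent / 1000)
  }, numeric(3))
  peak_rms <- max(feats["rms", ])
  if (peak_rms <= 0) stop("all-silence clip: no admissible analysis window")

  frame_n <- round(frame * clip$rate)
  sub_per_win <- floor((frame_n - g$sub_n) / g$hop_n) + 1L
  win_starts <- g$starts[g$starts + frame_n - 1L <= n]
  if (length(win_starts) == 0L) stop("clip shorter than the analysis frame")
  best <- NULL; best_cost <- Inf
  for (s in win_starts) {
    idx <- which(g$starts >= s & g$starts <= s + frame_n - g$sub_n)
    if (length(idx) < sub_per_win) next
    if (min(feats["rms", idx]) < 0.10 * peak_rms) next
    cost <- stats::var(feats["loge", idx]) + stats::var(feats["cent_khz", idx])
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- s }
  }
  if (is.null(best)) stop("all-silence clip: no admissible analysis window")
  structure(list(start = (best - 1L) / clip$rate, duration = frame_n / clip$rate,
                 samples = x[best:(best + frame_n - 1L)], rate = clip$rate),
            class = "steady_segment")
}

# Covariance-method linear prediction with robust trimming: the least-squares
# prediction equations are refit after discarding rows whose residuals are
# extreme outliers (median + k*MAD), i.e. the glottal-pulse instants. This
# removes the classic harmonic-locking bias of pitch-asynchronous LP at high
# f0 while leaving noise-like frames (near-Gaussian residuals, few outliers)
# essentially untrimmed, so unvoiced input is not over-fitted into spurious
# narrow resonances. Returns candidate (freq, bw) pairs from the roots of the
# prediction polynomial, ascending.
lp_candidates <- function(frame, rate, order, k_mad = 4, passes = 3L) {
  n <- length(frame)
  if (n <= 2 * order) return(NULL)
  X <- vapply(seq_len(order), function(k) frame[(order + 1 - k):(n - k)],
              numeric(n - order))
  yv <- frame[(order + 1):n]
  keep <- rep(TRUE, length(yv))
  a <- NULL
  for (i in seq_len(passes)) {
    a <- tryCatch(qr.solve(X[keep, , drop = FALSE], yv[keep]),
                  error = function(e) NULL)
    if (is.null(a)) return(NULL)
    if (i < passes) {
      r <- abs(yv - drop(X %*% a))
      nk <- r <= stats::median(r) + k_mad * stats::mad(r)
      if (sum(nk) < 4 * order) break
      keep <- nk
    }
  }
  rts <- polyroot(c(-rev(a), 1))
  ang <- Arg(rts)
  keep_r <- ang > 0
  data.frame(freq = ang[keep_r] * rate / (2 * pi),
             bw = -rate / pi * log(pmax(Mod(rts[keep_r]), 1e-12)),
             mod = Mod(rts[keep_r]))[order(ang[keep_r]), ]
}

# Fundamental-frequency estimate via the real cepstrum of the whole segment;
# used only to set the spectral-envelope smoothing width for fft512.
cepstral_f0 <- function(x, rate, lo = 80, hi = 400) {
  n2 <- 2^ceiling(log2(length(x)))
  w <- x * signal::hamming(length(x))
  logmag <- log(Mod(stats::fft(c(w, numeric(n2 - length(w))))) + 1e-9)
  cep <- Re(stats::fft(logmag, inverse = TRUE)) / n2
  q <- round(rate / hi):round(rate / lo)
  q <- q[q >= 2 & q < n2 / 2]
  rate / q[which.max(cep[q + 1])]
}

# 512-point spectral-envelope peak picking: zero-padded 512-point power
# spectrum of the (mean-removed, Hamming-windowed) subframe, smoothed by a
# moving average of one harmonic spacing -- whose frequency response has a
# null exactly at the harmonic ripple -- then local maxima with at least
# `prom_db` dB of prominence, refined by parabolic interpolation.
fft512_candidates <- function(frame, rate, hw, prom_db = 2) {
  nfft <- 512L
  if (length(frame) > nfft) {
    mid <- floor((length(frame) - nfft) / 2)
    frame <- frame[(mid + 1):(mid + nfft)]
  }
  fr <- (frame - mean(frame)) * signal::hamming(length(frame))
  pw <- Mod(stats::fft(c(fr, numeric(nfft - length(fr)))))[1:(nfft / 2)]^2
  m <- length(pw)
  hw <- max(1L, min(as.integer(hw), m %/% 4L))
  padded <- c(rev(pw[2:(hw + 1)]), pw, rev(pw[(m - hw):(m - 1)]))
  sm <- as.numeric(stats::filter(padded, rep(1 / (2 * hw + 1), 2 * hw + 1),
                                 sides = 2))[(hw + 1):(hw + m)]
  env <- 10 * log10(sm + 1e-12)
  k <- 2:(m - 1)
  pk <- k[env[k] > env[k - 1] & env[k] >= env[k + 1]]
  if (length(pk) == 0L) return(NULL)
  # peak prominence: height above the higher of the two key saddles (the
  # minima separating the peak from taller terrain on each side)
  prom <- vapply(pk, function(i) {
    lft <- env[1:(i - 1)]
    hi_l <- which(lft > env[i])
    min_l <- if (length(hi_l)) min(env[max(hi_l):(i - 1)]) else min(lft)
    rgt <- env[(i + 1):m]
    hi_r <- which(rgt > env[i])
    min_r <- if (length(hi_r)) min(env[(i + 1):(i + min(hi_r))]) else min(rgt)
    env[i] - max(min_l, min_r)
  }, numeric(1))
  pk <- pk[prom >= prom_db]
  if (length(pk) == 0L) return(NULL)
  delta <- 0.5 * (env[pk - 1] - env[pk + 1]) /
    (env[pk - 1] - 2 * env[pk] + env[pk + 1] + 1e-12)
  delta[!is.finite(delta) | abs(delta) > 1] <- 0
  binw <- rate / nfft
  data.frame(freq = (pk - 1 + delta) * binw, bw = NA_real_, mod = NA_real_)
}

#' Estimate F1/F2 from a steady vowel segment
#'
#' Default method `"lp"`: the segment is downsampled to twice the gender
#' formant ceiling (5,000 Hz male / 5,500 Hz female), pre-emphasized (0.97) and
#' cut into 25-ms subframes; each subframe undergoes covariance-method linear
#' prediction of order `2 + rate_after_downsampling / 1000` with robust
#' outlier trimming of the glottal-pulse rows, and formant candidates are the root
#' angles with bandwidth < 400 Hz and modulus > 0.7, sorted ascending. The
#' per-subframe (F1, F2) pairs are aggregated by the median. Method `"fft512"`
#' works on the same downsampled, pre-emphasized subframes but replaces linear
#' prediction with spectral-envelope peak picking on a 512-point power
#' spectrum, smoothed over one harmonic spacing (fundamental estimated once
#' per segment by cepstrum) and restricted to peaks with at least 2 dB of
#' prominence. Its resolution is bounded by the FFT bin width and the analysis
#' window, so closely spaced formants (open vowels at high fundamental) can
#' merge; that limitation is why `"lp"` is the default. Both report quality =
#' fraction of subframes yielding at least two admissible formants.
#'
#' @param seg a `steady_segment`.
#' @param method "lp" (default) or "fft512".
#' @param gender "male" or "female" (sets the formant ceiling).
#' @param ceiling optional explicit formant ceiling in Hz.
#' @param min_freq lowest admissible formant frequency (default 90 Hz).
#' @param max_bw widest admissible bandwidth for `lp` (default 400 Hz).
#' @return list with `F1`, `F2`, `quality`, `method`, and `candidates_per_subframe`.
#' @export
estimate_formants <- function(seg, method = c("lp", "fft512"),
                              gender = c("male", "female"), ceiling = NULL,
                              min_freq = 90, max_bw = 400) {
  stopifnot(inherits(seg, "steady_segment"))
  method <- match.arg(method)
  gender <- match.arg(gender)
  if (is.null(ceiling)) ceiling <- if (gender == "male") 5000 else 5500

  fs <- 2 * ceiling
  x <- resample_to(seg$samples, seg$rate, fs)
  x <- c(x[1], x[-1] - 0.97 * x[-length(x)])  # pre-emphasis
  if (method == "lp") {
    ord <- 2 + round(fs / 1000)
  } else {
    hw <- max(1L, round((cepstral_f0(x, fs) / (fs / 512) - 1) / 2))
  }
  g <- subframe_grid(length(x), fs)
  pairs <- lapply(g$starts, function(s) {
    fr <- x[s:(s + g$sub_n - 1L)]
    cand <- if (method == "lp") lp_candidates(fr, fs, ord) else fft512_candidates(fr, fs, hw)
    if (is.null(cand)) return(NULL)
    ok <- cand$freq > min_freq & cand$freq < 0.95 * ceiling
    if (method == "lp") ok <- ok & cand$bw < max_bw & cand$mod > 0.7
    f <- sort(cand$freq[ok])
    if (length(f) >= 2) f[1:2] else NULL
  })
  good <- !vapply(pairs, is.null, logical(1))
  quality <- mean(good)
  if (!any(good)) stop("formant estimation failed: no subframe yielded two admissible formants")
  m <- do.call(rbind, pairs[good])
  f1 <- stats::median(m[, 1]); f2 <- stats::median(m[, 2])
  if (f1 >= f2) stop("formant estimation failed: aggregated F1 >= F2")
  list(F1 = f1, F2 = f2, quality = quality, method = method,
       candidates_per_subframe = sum(good))
}

#' Extract a formant profile from per-vowel recordings
#'
#' Runs steady-segment selection and formant estimation on every repetition of
#' each corner vowel and aggregates repetitions by the median, yielding one
#' validated `formant_profile` per session.
#'
#' @param clips named list with elements "A", "I", "U"; each either a single
#'   `audio_clip` or a list of repetition clips.
#' @param speaker,gender,timepoint session metadata.
#' @param method passed to [estimate_formants()].
#' @param frame steady-segment length in seconds.
#' @return a `formant_profile`.
#' @export
extract_profile <- function(clips, speaker, gender, timepoint = "pre",
                            method = "lp", frame = 0.200) {
  need <- c("A", "I", "U")
  if (!all(need %in% names(clips)))
    stop("missing vowel clip(s): ", paste(setdiff(need, names(clips)), collapse = ", "))
  freq <- matrix(NA_real_, 3, 2, dimnames = list(need, c("F1", "F2")))
  qual <- stats::setNames(numeric(3), need)
  for (v in need) {
    reps <- clips[[v]]
    if (inherits(reps, "audio_clip")) reps <- list(reps)
    est <- tryCatch(
      lapply(reps, function(cl)
        estimate_formants(find_steady_segment(cl, frame), method = method, gender = gender)),
      error = function(e) stop("formant extraction failed for vowel ", v, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    freq[v, "F1"] <- stats::median(vapply(est, `[[`, numeric(1), "F1"))
    freq[v, "F2"] <- stats::median(vapply(est, `[[`, numeric(1), "F2"))
    qual[v] <- mean(vapply(est, `[[`, numeric(1), "quality"))
  }
  formant_profile(speaker, gender, timepoint, freq, quality = qual, method = method)
}
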