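#' @name formant-metrics
#' @title Derived vowel formant metrics
#'
#' @description
#' Scalar metrics of lingual mobility computed from the F1/F2 of the three
#' corner vowels:
#' \itemize{
#'   \item FCR, the formant centralization ratio
#'     \eqn{(F2_u + F2_a + F1_i + F1_u) / (F2_i + F1_a)} (Sapir's dysarthria
#'     measure): dimensionless, scale-invariant, rises as the vowel triangle
#'     collapses, equals exactly 2 at a point-collapsed triangle.
#'   \item VSA, the vowel space area: the triangle area spanned by the three
#'     vowels in the F1-F2 plane, in Hz^2; 0 when the vowels are collinear.
#'   \item Joos-VSA: base-10 logarithm of VSA; undefined (NA) when VSA = 0.
#'   \item CD, the compact-diffuse correlate: F2(v) - F1(v), the formant
#'     proximity of one vowel (compact spectra have close formants).
#'   \item GA, the grave-acute correlate: (F1(v) + F2(v))/2, the spectral
#'     balance of one vowel (grave spectra concentrate energy low).
#' }
#' CD and GA are config-swappable: pass alternative functions of (F1, F2) via
#' `cd_fun` / `ga_fun` in [build_feature_vector()].
NULL

#' Formant centralization ratio
#' @param profile a `formant_profile`.
#' @return dimensionless FCR.
#' @rdname formant-metrics
#' @export
compute_fcr <- function(profile) {
  f <- profile$freq
  if (any(!is.finite(f))) stop("missing formant in profile")
  (f["U", "F2"] + f["A", "F2"] + f["I", "F1"] + f["U", "F1"]) /
    (f["I", "F2"] + f["A", "F1"])
}

#' Vowel space area (Hz^2)
#' @rdname formant-metrics
#' @export
compute_vsa <- function(profile) {
  f <- profile$freq
  0.5 * abs(f["I", "F1"] * (f["A", "F2"] - f["U", "F2"]) +
            f["A", "F1"] * (f["U", "F2"] - f["I", "F2"]) +
            f["U", "F1"] * (f["I", "F2"] - f["A", "F2"]))
}

#' Base-10 log vowel space area
#' @rdname formant-metrics
#' @export
compute_joos_vsa <- function(profile) {
  vsa <- compute_vsa(profile)
  if (vsa <= 0) return(NA_real_)  # collinear vowels: undefined, reported missing
  log10(vsa)
}

#' Compact-diffuse correlate of one vowel (Hz)
#' @param vowel "A", "I" or "U".
#' @param cd_fun,ga_fun functions of (F1, F2) overriding the default formulas.
#' @rdname formant-metrics
#' @export
compute_cd <- function(profile, vowel, cd_fun = function(f1, f2) f2 - f1) {
  vowel <- match.arg(vowel, c("A", "I", "U"))
  cd_fun(profile$freq[vowel, "F1"], profile$freq[vowel, "F2"])
}

#' Grave-acute correlate of one vowel (Hz)
#' @rdname formant-metrics
#' @export
compute_ga <- function(profile, vowel, ga_fun = function(f1, f2) (f1 + f2) / 2) {
  vowel <- match.arg(vowel, c("A", "I", "U"))
  ga_fun(profile$freq[vowel, "F1"], profile$freq[vowel, "F2"])
}

#' Canonical order of the 15 acoustic features
#' @return character vector of the 15 feature names.
#' @export
feature_names <- function() {
  c("F1_A", "F1_I", "F1_U", "F2_A", "F2_I", "F2_U",
    "FCR", "VSA", "JoosVSA",
    "CD_A", "CD_I", "CD_U", "GA_A", "GA_I", "GA_U")
}

#' Build the 15-feature acoustic vector of one session
#'
#' Assembles the six raw formants (copied through unchanged) and the nine
#' derived metrics into a named numeric vector in canonical order. A derived
#' value that is undefined (e.g. Joos-VSA of a collinear triangle) is carried
#' as NA; sessions with any NA feature are excluded from model training by
#' [label_join()] but remain in bookkeeping.
#'
#' @param profile a `formant_profile`.
#' @param cd_fun,ga_fun optional overrides for the CD/GA formulas.
#' @return named numeric vector of length 15.
#' @export
build_feature_vector <- function(profile, cd_fun = function(f1, f2) f2 - f1,
                                 ga_fun = function(f1, f2) (f1 + f2) / 2) {
  f <- profile$freq
  out <- c(
    F1_A = f["A", "F1"], F1_I = f["I", "F1"], F1_U = f["U", "F1"],
    F2_A = f["A", "F2"], F2_I = f["I", "F2"], F2_U = f["U", "F2"],
    FCR = compute_fcr(profile), VSA = compute_vsa(profile),
    JoosVSA = compute_joos_vsa(profile),
    CD_A = compute_cd(profile, "A", cd_fun), CD_I = compute_cd(profile, "I", cd_fun),
    CD_U = compute_cd(profile, "U", cd_fun),
    GA_A = compute_ga(profile, "A", ga_fun), GA_I = compute_ga(profile, "I", ga_fun),
    GA_U = compute_ga(profile, "U", ga_fun)
  )
  out[feature_names()]
}

#' Feature table from a list of profiles
#'
#' One row per session: metadata columns followed by the 15 canonical feature
#' columns.
#'
#' @param profiles list of `formant_profile` objects.
#' @param meta optional data.frame of extra per-session columns (same order).
#' @return data.frame with columns `session`, `speaker`, `gender`, `timepoint`
#'   and the 15 features.
#' @export
feature_table <- function(profiles, meta = NULL) {
  rows <- lapply(profiles, build_feature_vector)
  tab <- as.data.frame(do.call(rbind, rows))
  base <- data.frame(
    session = vapply(profiles, function(p) paste(p$speaker, p$timepoint, sep = "_"), character(1)),
    speaker = vapply(profiles, function(p) as.character(p$speaker), character(1)),
    gender = vapply(profiles, function(p) p$gender, character(1)),
    timepoint = vapply(profiles, function(p) p$timepoint, character(1)),
    stringsAsFactors = FALSE
  )
  out <- cbind(base, tab)
  if (!is.null(meta)) out <- cbind(out, meta)
  rownames(out) <- NULL
  out
}
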