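#' The 12-syllable perceptual stimulus corpus
#'
#' Twelve Mandarin CV/CVV monosyllables built from nine tongue-dominant
#' consonants: alveolar /d/, /t/, /n/, /l/; alveolo-palatal /j/, /q/, /x/;
#' velar /g/, /k/. Some consonants appear in two vowel contexts to fill the 12
#' slots. The corpus is configuration data, not code: pass a replacement
#' data.frame with the same columns to use a different stimulus set.
#'
#' @param corpus optional replacement data.frame with columns `syllable`,
#'   `consonant`, `place`, `vowel`.
#' @return data.frame with 12 rows and columns `syllable`, `consonant`,
#'   `place` (alveolar / alveolo-palatal / velar), `vowel`.
#' @export
syllable_corpus <- function(corpus = NULL) {
  if (is.null(corpus)) {
    corpus <- data.frame(
      syllable  = c("da", "di", "ta", "ni", "lu", "ji", "qi", "xi", "xu", "ga", "gu", "ku"),
      consonant = c("d", "d", "t", "n", "l", "j", "q", "x", "x", "g", "g", "k"),
      place     = c("alveolar", "alveolar", "alveolar", "alveolar", "alveolar",
                    "alveolo-palatal", "alveolo-palatal", "alveolo-palatal",
                    "alveolo-palatal", "velar", "velar", "velar"),
      vowel     = c("a", "i", "a", "i", "u", "i", "i", "i", "u", "a", "u", "u"),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("syllable", "consonant", "place", "vowel") %in% names(corpus)))
  allowed <- c("d", "t", "n", "l", "j", "q", "x", "g", "k")
  if (!all(corpus$consonant %in% allowed))
    stop("corpus consonants must be drawn from the nine tongue-dominant phonemes")
  if (anyDuplicated(corpus$syllable)) stop("syllable ids must be unique")
  if (!all(c("alveolar", "alveolo-palatal", "velar") %in% corpus$place))
    stop("every place group must be non-empty")
  corpus
}

#' Percent consonants correct
#'
#' Group-level proportion of correctly articulated consonant trials, as a
#' percentage with trial counts. Records are a long data.frame of binary
#' outcomes (1 = correct, 0 = deviated), one row per (session, syllable).
#'
#' @param records data.frame with columns `session`, `syllable`, `outcome` and
#'   (for gender grouping) `gender`.
#' @param group_by "overall", "place" or "gender_place".
#' @param corpus syllable corpus (maps syllable to place group).
#' @return data.frame with grouping columns, `pcc` (percent), `correct`, `trials`.
#' @export
pcc <- function(records, group_by = c("overall", "place", "gender_place"),
                corpus = syllable_corpus()) {
  group_by <- match.arg(group_by)
  if (is.null(records) || nrow(records) == 0L) stop("no perceptual records")
  if (!all(records$outcome %in% c(0, 1))) stop("outcomes must be 0/1")
  records$place <- corpus$place[match(records$syllable, corpus$syllable)]
  if (anyNA(records$place)) stop("records contain syllables not in the corpus")
  key <- switch(group_by,
    overall = list(group = rep("overall", nrow(records))),
    place = list(place = records$place),
    gender_place = list(gender = records$gender, place = records$place))
  agg <- stats::aggregate(records$outcome, by = key,
                          FUN = function(o) c(correct = sum(o), trials = length(o)))
  out <- data.frame(agg[-ncol(agg)], agg$x, check.names = FALSE)
  out$pcc <- 100 * out$correct / out$trials
  out
}

#' Join acoustic features with perceptual labels for one syllable
#'
#' Builds, per gender, the labeled dataset for one syllable's classifier: the
#' 15-column feature matrix and a 0/1 label vector (1 = correct). Sessions with
#' any missing feature are dropped with a logged count; session ids must
#' overlap.
#'
#' @param features feature table from [feature_table()] (needs `session`,
#'   `gender`, feature columns).
#' @param records long perceptual record data.frame (`session`, `syllable`,
#'   `outcome`).
#' @param syllable_id which syllable's outcomes to use as labels.
#' @return named list by gender; each element has `x` (matrix n x 15), `y`
#'   (0/1 vector), `session`, `n_dropped`.
#' @export
label_join <- function(features, records, syllable_id) {
  rec <- records[records$syllable == syllable_id, c("session", "outcome")]
  merged <- merge(features, rec, by = "session")
  if (nrow(merged) == 0L) stop("no overlapping sessions between features and records")
  fn <- feature_names()
  out <- list()
  for (g in unique(merged$gender)) {
    sub <- merged[merged$gender == g, , drop = FALSE]
    x <- as.matrix(sub[, fn, drop = FALSE])
    complete <- stats::complete.cases(x)
    n_dropped <- sum(!complete)
    if (n_dropped > 0)
      message(sprintf("label_join: dropped %d session(s) with missing features (%s, %s)",
                      n_dropped, g, syllable_id))
    out[[g]] <- list(x = x[complete, , drop = FALSE],
                     y = sub$outcome[complete],
                     session = sub$session[complete],
                     n_dropped = n_dropped)
  }
  out
}
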