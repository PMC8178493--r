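#' Severity model linking disease burden to speech outcomes
#'
#' Parameterizes the generator's causal chain: (i) a centralization weight
#' `lambda` that grows with clinical T class pre-operatively and gains a
#' resection-dependent increment post-operatively; (ii) a logistic link from
#' the session's FCR to the probability of a deviated consonant articulation,
#' with per-place offsets (alveolo-palatal highest, so that group shows the
#' lowest percent consonants correct); and (iii) a linear latent link from FCR
#' to the 30 questionnaire items. The slope `b1` is constrained non-negative so
#' a larger FCR never lowers the misarticulation probability, matching the
#' all-negative SVM weights the screening stage is expected to recover.
#'
#' @param lambda_t named centralization weights per T class (T0..T4), pre-op;
#'   must be non-decreasing in T.
#' @param lambda_surg named post-op increments per resection extent.
#' @param lambda_sd between-subject SD of the centralization weight.
#' @param b0,b1,center logistic intercept, slope (>= 0) and FCR centering.
#' @param place_offset named logit offsets per consonant place group.
#' @param shi_intercept,shi_slope,shi_subject_sd,shi_item_sd latent item-scale
#'   intercept/slope on FCR and the two noise SDs.
#' @param formant_jitter_sd per-session additive formant jitter (Hz).
#' @param measurement_sd parametric-observation measurement noise (Hz).
#' @param speaker_scale_sd between-subject SD of the multiplicative
#'   vocal-tract scale factor applied to all six formants. Within-gender
#'   formant scaling varies on the order of 10% between adult speakers; this
#'   anatomical variation corrupts every absolute-frequency feature while the
#'   dimensionless FCR cancels it, which is the property that makes FCR
#'   recoverable as the dominant marker.
#' @param vowel_shape_sd between-subject log-scale SD of per-formant
#'   idiosyncrasy (each of the six corner-vowel formants gets its own
#'   multiplicative factor). This models idiolectal vowel-quality
#'   differences; because the articulation link is driven by the FCR of the
#'   formants a speaker actually produces, this variation feeds the outcome
#'   through FCR while decorrelating the other acoustic features from it.
#' @return an object of class `severity_model`.
#' @export
severity_model <- function(lambda_t = c(T0 = 0, T1 = 0.05, T2 = 0.12, T3 = 0.22, T4 = 0.32),
                           lambda_surg = c(PG = 0.08, HG = 0.15, `STG/TG` = 0.30),
                           lambda_sd = 0.04,
                           b0 = -1.2, b1 = 28, center = 1.0,
                           place_offset = c(alveolar = 0, `alveolo-palatal` = 0.8,
                                            velar = -0.4),
                           shi_intercept = -6.4, shi_slope = 8,
                           shi_subject_sd = 0.3, shi_item_sd = 0.5,
                           formant_jitter_sd = 15, measurement_sd = 5,
                           speaker_scale_sd = 0.12, vowel_shape_sd = 0.08) {
  if (is.unsorted(lambda_t)) stop("lambda_t must be non-decreasing in T class")
  if (any(lambda_t < 0) || any(lambda_t > 1)) stop("lambda_t must lie in [0, 1]")
  if (b1 < 0) stop("logistic slope b1 must be non-negative")
  structure(list(lambda_t = lambda_t, lambda_surg = lambda_surg, lambda_sd = lambda_sd,
                 b0 = b0, b1 = b1, center = center, place_offset = place_offset,
                 shi_intercept = shi_intercept, shi_slope = shi_slope,
                 shi_subject_sd = shi_subject_sd, shi_item_sd = shi_item_sd,
                 formant_jitter_sd = formant_jitter_sd, measurement_sd = measurement_sd,
                 speaker_scale_sd = speaker_scale_sd, vowel_shape_sd = vowel_shape_sd),
            class = "severity_model")
}

#' Probability of a deviated articulation given FCR
#' @param fcr formant centralization ratio.
#' @param place consonant place group.
#' @param model a `severity_model`.
#' @return probability in (0, 1).
#' @export
p_deviated <- function(fcr, place, model) {
  off <- model$place_offset[place]
  if (anyNA(off)) stop("unknown consonant place group")
  stats::plogis(model$b0 + model$b1 * (fcr - model$center) + unname(off))
}

#' Simulate the 12 binary syllable outcomes of one session
#'
#' Bernoulli draws per syllable with P(deviated) from the logistic link;
#' outcomes are coded 1 = correct, 0 = deviated. Deterministic given `seed`.
#'
#' @param fcr the session's formant centralization ratio.
#' @param model a `severity_model`.
#' @param seed integer seed (NULL to use the current RNG state).
#' @param corpus syllable corpus.
#' @return data.frame with columns `syllable`, `place`, `outcome`.
#' @export
simulate_perception <- function(fcr, model, seed = NULL, corpus = syllable_corpus()) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p_dev <- p_deviated(fcr, corpus$place, model)
  data.frame(syllable = corpus$syllable, place = corpus$place,
             outcome = 1L - stats::rbinom(nrow(corpus), 1L, p_dev),
             stringsAsFactors = FALSE)
}

#' Simulate the 30 questionnaire item scores of one session
#'
#' A latent severity `shi_intercept + shi_slope * fcr + subject noise` drives
#' all 30 items; each item adds independent noise and is rounded and clipped to
#' the 0-4 item scale. Because the speech and psychosocial subsets share the
#' latent, high internal consistency is induced by construction.
#'
#' @inheritParams simulate_perception
#' @param scale_max top of the item scale (default 4).
#' @return integer vector of 30 item scores.
#' @export
simulate_shi <- function(fcr, model, seed = NULL, scale_max = 4L) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  latent <- model$shi_intercept + model$shi_slope * fcr +
    stats::rnorm(1, sd = model$shi_subject_sd)
  items <- round(latent + stats::rnorm(30, sd = model$shi_item_sd))
  as.integer(pmin(scale_max, pmax(0L, items)))
}

# Largest-remainder allocation of n units over the given weights.
allocate_counts <- function(n, weights) {
  w <- weights / sum(weights)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * w - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Cohort generator configuration
#'
#' `role = "validation"` reproduces the prospective surgical cohort layout: 33
#' patients (20 male, 13 female) with the published T-class, resection,
#' reconstruction and flap margins, measured pre- and post-operatively, with
#' one deterministic loss to follow-up before the post-op session (hence 65
#' sessions and a 97% follow-up rate). `role = "screening"` yields a
#' cross-sectional single-timepoint mix of patients and healthy controls
#' (default 120 + 36 = 156 sessions) used to train the per-syllable
#' classifiers.
#'
#' @param role "validation" or "screening".
#' @param n_patients,n_controls cohort sizes (controls are healthy T0, pre only).
#' @param male_patients,male_controls male counts (remainder female).
#' @param t_male,t_female T1..T4 counts per gender (recycled proportionally if
#'   they do not sum to the gender count).
#' @param resect_male,resect_female PG/HG/STG-TG counts per gender.
#' @param recon_male,recon_female reconstructed counts per gender.
#' @param alt_male,alt_female ALT-flap counts among the reconstructed.
#' @param dropout number of patients lost before the post-op session
#'   (deterministically the last enrolled; must be < n_patients).
#' @param timepoints measurement occasions.
#' @param targets_male,targets_female `formant_targets` per gender.
#' @param model a `severity_model`.
#' @param observation "parametric" (measured formants = generated truth plus
#'   measurement noise) or "audio" (synthesize WAV per vowel and run the
#'   extraction stage).
#' @param rate,duration,f0_male,f0_female,noise_level audio parameters.
#' @param seed master seed (mandatory; all randomness derives from it).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(role = c("validation", "screening"),
                          n_patients = NULL, n_controls = NULL,
                          male_patients = NULL, male_controls = NULL,
                          t_male = c(T1 = 1, T2 = 7, T3 = 5, T4 = 7),
                          t_female = c(T1 = 3, T2 = 5, T3 = 1, T4 = 4),
                          resect_male = c(PG = 6, HG = 9, `STG/TG` = 5),
                          resect_female = c(PG = 4, HG = 7, `STG/TG` = 2),
                          recon_male = 18, recon_female = 9,
                          alt_male = 15, alt_female = 8,
                          dropout = NULL, timepoints = NULL,
                          targets_male = formant_targets("male"),
                          targets_female = formant_targets("female"),
                          model = severity_model(),
                          observation = c("parametric", "audio"),
                          rate = 44100, duration = 1,
                          f0_male = 120, f0_female = 210, noise_level = 0.01,
                          seed = 1L) {
  role <- match.arg(role)
  observation <- match.arg(observation)
  if (is.null(n_patients)) n_patients <- if (role == "validation") 33L else 120L
  if (is.null(n_controls)) n_controls <- if (role == "validation") 0L else 36L
  if (is.null(male_patients))
    male_patients <- if (role == "validation") round(20 / 33 * n_patients)
                     else round(62 / 120 * n_patients)
  if (is.null(male_controls)) male_controls <- floor(n_controls / 2)
  if (is.null(dropout)) dropout <- if (role == "validation") 1L else 0L
  if (is.null(timepoints)) timepoints <- if (role == "validation") c("pre", "post") else "pre"
  if (n_patients < 1) stop("n_patients must be at least 1")
  if (dropout >= n_patients) stop("dropout count must be smaller than n_patients")
  if (duration < 1) stop("sustained vowels must last at least 1 s")
  structure(list(role = role, n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 male_patients = as.integer(male_patients),
                 male_controls = as.integer(male_controls),
                 t_male = t_male, t_female = t_female,
                 resect_male = resect_male, resect_female = resect_female,
                 recon_male = recon_male, recon_female = recon_female,
                 alt_male = alt_male, alt_female = alt_female,
                 dropout = as.integer(dropout), timepoints = timepoints,
                 targets = list(male = targets_male, female = targets_female),
                 model = model, observation = observation,
                 rate = rate, duration = duration,
                 f0 = c(male = f0_male, female = f0_female),
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic patient roster with the configured covariate margins. Within
# each gender, resection extent is assigned in step with T class (sorted
# jointly) so severity and surgical extent co-vary; reconstruction fills from
# the largest resections down; ALT flaps fill the reconstructed from the top.
# Females are enrolled first so the last enrolled patient (the deterministic
# dropout) is male.
build_roster <- function(config) {
  one_gender <- function(n, gender, t_counts, r_counts, n_recon, n_alt) {
    tc <- allocate_counts(n, t_counts)
    rc <- allocate_counts(n, r_counts)
    tcl <- rep(1:4, times = tc)
    res <- rep(names(rc), times = rc)
    recon <- rep(FALSE, n)
    if (n > 0 && n_recon > 0) recon[seq(n - min(n_recon, n) + 1, n)] <- TRUE
    flap <- rep("none", n)
    ridx <- which(recon)
    if (length(ridx) > 0) {
      n_alt <- min(n_alt, length(ridx))
      flap[ridx] <- c(rep("other", length(ridx) - n_alt), rep("ALT", n_alt))
    }
    data.frame(gender = rep(gender, n), tclass = tcl, resection = res,
               reconstruction = recon, flap = flap, stringsAsFactors = FALSE)
  }
  f <- one_gender(config$n_patients - config$male_patients, "female",
                  config$t_female, config$resect_female,
                  config$recon_female, config$alt_female)
  m <- one_gender(config$male_patients, "male",
                  config$t_male, config$resect_male,
                  config$recon_male, config$alt_male)
  pts <- rbind(f, m)
  pts <- data.frame(speaker = sprintf("P%02d", seq_len(nrow(pts))), pts,
                    role = "patient", stringsAsFactors = FALSE)
  if (config$n_controls > 0) {
    cg <- c(rep("male", config$male_controls),
            rep("female", config$n_controls - config$male_controls))
    ctrl <- data.frame(speaker = sprintf("C%02d", seq_len(config$n_controls)),
                       gender = cg, tclass = 0L, resection = "none",
                       reconstruction = FALSE, flap = "none", role = "control",
                       stringsAsFactors = FALSE)
    pts <- rbind(pts, ctrl)
  }
  pts$age <- round(pmin(75, pmax(18, stats::rnorm(nrow(pts), mean = 52, sd = 9))))
  pts
}

#' Simulate a full cohort: session table, perceptual outcomes, questionnaires
#'
#' Draws per-subject centralization weights from the severity model, generates
#' per-session formant profiles (parametrically, or by synthesizing and
#' re-extracting WAV audio), simulates the 12 syllable outcomes and 30
#' questionnaire items from the session's FCR, and assembles the 15-feature
#' session table with clinical covariates. Controls contribute pre sessions
#' only; the configured number of last-enrolled patients drop out before the
#' post-op session. Fully reproducible from `config$seed`.
#'
#' @param config a `cohort_config`.
#' @param audio_dir directory to write per-vowel WAV files
#'   (`{subject}_{timepoint}_{vowel}.wav`) when `observation = "audio"`;
#'   NULL keeps the audio in memory.
#' @return list with `sessions` (feature + covariate data.frame), `perception`
#'   (long outcome data.frame), `shi` (sessions x 30 integer matrix),
#'   `roster` (per-subject covariates), `config`.
#' @export
simulate_cohort <- function(config, audio_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  roster <- build_roster(config)
  model <- config$model
  corpus <- syllable_corpus()
  if (!is.null(audio_dir) && !dir.exists(audio_dir))
    dir.create(audio_dir, recursive = TRUE)

  dropped <- character(0)
  if (config$dropout > 0) {
    pat <- roster$speaker[roster$role == "patient"]
    dropped <- utils::tail(pat, config$dropout)
  }

  profiles <- list(); meta <- list(); percep <- list(); shi <- list()
  for (i in seq_len(nrow(roster))) {
    subj <- roster[i, ]
    lam_dev <- stats::rnorm(1, sd = model$lambda_sd)
    scale_f <- stats::rnorm(1, mean = 1, sd = model$speaker_scale_sd)
    shape_f <- exp(matrix(stats::rnorm(6, sd = model$vowel_shape_sd), 3, 2))
    f0 <- stats::rnorm(1, mean = config$f0[subj$gender], sd = 8)
    tps <- if (subj$role == "control") "pre" else config$timepoints
    if (subj$speaker %in% dropped) tps <- setdiff(tps, "post")
    for (tp in tps) {
      lam <- model$lambda_t[paste0("T", subj$tclass)] +
        if (tp == "post") model$lambda_surg[subj$resection] else 0
      lam <- min(1, max(0, lam + lam_dev))
      tg <- centralize(config$targets[[subj$gender]], lam)
      freq <- scale_f * shape_f * tg$freq +
        matrix(stats::rnorm(6, sd = model$formant_jitter_sd), 3, 2)
      freq <- enforce_profile_validity(freq)
      fcr_true <- (freq["U", "F2"] + freq["A", "F2"] + freq["I", "F1"] + freq["U", "F1"]) /
        (freq["I", "F2"] + freq["A", "F1"])

      if (config$observation == "audio") {
        tg_obs <- config$targets[[subj$gender]]
        tg_obs$freq <- freq
        clips <- lapply(c(A = "A", I = "I", U = "U"), function(v)
          synthesize_vowel(v, tg_obs, f0 = f0, duration = config$duration,
                           rate = config$rate, noise_level = config$noise_level,
                           seed = sample.int(.Machine$integer.max, 1)))
        if (!is.null(audio_dir)) {
          for (v in names(clips))
            write_wav(clips[[v]], file.path(audio_dir,
              sprintf("%s_%s_%s.wav", subj$speaker, tp, v)))
        }
        prof <- extract_profile(clips, subj$speaker, subj$gender, tp)
      } else {
        meas <- freq + matrix(stats::rnorm(6, sd = model$measurement_sd), 3, 2)
        meas <- enforce_profile_validity(meas)
        prof <- formant_profile(subj$speaker, subj$gender, tp, meas,
                                method = "parametric")
      }
      sid <- paste(subj$speaker, tp, sep = "_")
      profiles[[sid]] <- prof
      meta[[sid]] <- data.frame(tclass = subj$tclass, resection = subj$resection,
                                reconstruction = subj$reconstruction,
                                flap = subj$flap, role = subj$role,
                                fcr_true = fcr_true, stringsAsFactors = FALSE)
      pc <- simulate_perception(fcr_true, model,
                                seed = sample.int(.Machine$integer.max, 1),
                                corpus = corpus)
      pc <- data.frame(session = sid, gender = subj$gender, pc,
                       stringsAsFactors = FALSE)
      percep[[sid]] <- pc
      shi[[sid]] <- simulate_shi(fcr_true, model,
                                 seed = sample.int(.Machine$integer.max, 1))
    }
  }
  sessions <- feature_table(profiles, meta = do.call(rbind, meta))
  shi_mat <- do.call(rbind, shi)
  rownames(shi_mat) <- sessions$session
  colnames(shi_mat) <- sprintf("item%02d", 1:30)
  list(sessions = sessions, perception = do.call(rbind, c(percep, make.row.names = FALSE)),
       shi = shi_mat, roster = roster, config = config)
}

# Jittered frequencies can in principle violate profile invariants at extreme
# draws; nudge them back (keeps F1 < F2 and positivity without biasing typical
# draws).
enforce_profile_validity <- function(freq) {
  freq <- pmax(freq, 60)
  bad <- freq[, 2] <= freq[, 1]
  if (any(bad)) freq[bad, 2] <- freq[bad, 1] + 30
  freq
}

#' Follow-up success rate of a simulated cohort
#' @param cohort result of [simulate_cohort()].
#' @return percentage of patients retained at post-op, rounded to an integer.
#' @export
followup_rate <- function(cohort) {
  pats <- cohort$roster$speaker[cohort$roster$role == "patient"]
  post <- unique(cohort$sessions$speaker[cohort$sessions$timepoint == "post"])
  round(100 * length(intersect(pats, post)) / length(pats))
}
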