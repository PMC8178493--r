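#' Train one syllable's linear SVM classifier
#'
#' Fits a soft-margin linear support-vector machine predicting the binary
#' articulation outcome (1 = correct, 0 = deviated) of one syllable from the 15
#' acoustic features of one gender's sessions. Features are z-scored with the
#' stored parameters before fitting, so the per-feature weights are comparable
#' across features; the weight vector is oriented so a positive decision score
#' predicts label 1, hence a feature whose increase raises the misarticulation
#' probability receives a negative weight. Cross-validated performance comes
#' from seeded stratified k-fold (default 10-fold).
#'
#' @param x n x 15 feature matrix with canonical column names.
#' @param y 0/1 labels (1 = correct).
#' @param folds number of cross-validation folds (reduced to n with a warning
#'   when n < folds; 0 skips cross-validation).
#' @param cost soft-margin box constraint C.
#' @param seed seed controlling the fold assignment.
#' @param gender,syllable optional metadata carried on the model.
#' @return an object of class `svm_model`: weights, bias, standardization
#'   parameters, CV metrics, support-vector count.
#' @export
train_syllable_model <- function(x, y, folds = 10, cost = 1, seed = 1L,
                                 gender = NA_character_, syllable = NA_character_) {
  x <- as.matrix(x)
  if (!identical(colnames(x), feature_names()))
    stop("feature columns must be the 15 canonical features in canonical order")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("degenerate syllable: only one outcome class present")
  if (min(table(y)) < 2) stop("degenerate syllable: need at least 2 rows per class")
  n <- nrow(x)
  if (folds > 0 && n < folds) {
    warning(sprintf("reducing folds from %d to %d (n = %d)", folds, n, n))
    folds <- n
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1  # constant feature: carries zero weight either way
  xs <- scale(x, center = mu, scale = sdv)

  fit_one <- function(xtr, ytr) {
    m <- e1071::svm(xtr, factor(ytr, levels = c(0, 1)), kernel = "linear",
                    cost = cost, scale = FALSE)
    w <- drop(t(m$coefs) %*% m$SV)
    b <- -m$rho
    # orient so that score > 0 <=> predicted class "1"
    pred <- predict(m, xtr)
    score <- drop(xtr %*% w) + b
    if (mean((score > 0) == (pred == "1")) < 0.5) { w <- -w; b <- -b }
    list(w = w, b = b, n_sv = nrow(m$SV))
  }
  full <- fit_one(xs, y)

  cv <- NULL
  if (folds > 0) {
    set.seed(as.integer(seed))
    fold_id <- integer(n)
    for (cl in c(0, 1)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    score <- numeric(n)
    ok <- rep(TRUE, n)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      if (length(unique(y[tr])) < 2) { ok[!tr] <- FALSE; next }
      fk <- fit_one(xs[tr, , drop = FALSE], y[tr])
      score[!tr] <- drop(xs[!tr, , drop = FALSE] %*% fk$w) + fk$b
    }
    cv <- binary_metrics(score[ok], y[ok])
  }
  structure(list(gender = gender, syllable = syllable,
                 weights = stats::setNames(full$w, feature_names()), bias = full$b,
                 center = mu, scale = sdv, cv = cv, n_sv = full$n_sv,
                 cost = cost, folds = folds, seed = as.integer(seed)),
            class = "svm_model")
}

# Threshold-free + thresholded classification metrics from decision scores.
# Undefined ratios (zero denominator) are NA, never 0.
binary_metrics <- function(score, y) {
  pred <- as.integer(score > 0)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  auc <- if (length(unique(y)) == 2) roc_curve(score, y)$auc else NA_real_
  list(accuracy = (tp + tn) / length(y), auc = auc,
       sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn))
}

#' Apply a trained model to new sessions
#'
#' Standardizes the test features with the parameters stored at training time,
#' applies the linear decision rule, and reports accuracy, AUC, sensitivity,
#' specificity, PPV and NPV (positive class = correct articulation).
#'
#' @param model an `svm_model`.
#' @param x test feature matrix (canonical 15 columns).
#' @param y 0/1 test labels.
#' @return list of metrics; ratios with zero denominator are NA.
#' @export
evaluate_model <- function(model, x, y) {
  x <- as.matrix(x)
  if (!identical(colnames(x), feature_names()))
    stop("test features do not match the 15 canonical feature names")
  xs <- scale(x, center = model$center, scale = model$scale)
  score <- drop(xs %*% model$weights) + model$bias
  binary_metrics(score, y)
}

#' Assemble the 15 x 12 per-gender weight matrix
#'
#' Rows are the 15 acoustic features in canonical order, columns the 12
#' syllables in corpus order; entries are the standardized-scale SVM weights
#' ("LPCs"). This is the exportable heatmap data.
#'
#' @param models named list of `svm_model`s, one per syllable.
#' @param corpus syllable corpus fixing the column order.
#' @return 15 x 12 numeric matrix.
#' @export
lpc_matrix <- function(models, corpus = syllable_corpus()) {
  missing <- setdiff(corpus$syllable, names(models))
  if (length(missing) > 0)
    stop("missing syllable model(s): ", paste(missing, collapse = ", "))
  m <- vapply(corpus$syllable, function(s) models[[s]]$weights,
              numeric(length(feature_names())))
  rownames(m) <- feature_names()
  m
}

#' Rank acoustic features by SVM weight magnitude
#'
#' Features are ranked by the mean absolute weight across syllable models
#' (columns); the rank-1 feature is the dominant marker. A per-feature sign
#' summary reports how many weights are negative — the expected pattern for a
#' marker that rises with misarticulation. Ties are broken by canonical feature
#' order; an all-zero matrix is flagged degenerate.
#'
#' @param mat a weight matrix with the 15 canonical rows (any column count, so
#'   per-gender matrices may be cbound before ranking).
#' @return list with `ranking` (data.frame: feature, mean_abs_weight, n_neg,
#'   n_pos, all_negative, rank), `dominant`, `degenerate`.
#' @export
rank_predictors <- function(mat) {
  stopifnot(identical(rownames(mat), feature_names()))
  score <- rowMeans(abs(mat))
  ord <- order(-score, seq_along(score))  # canonical order breaks ties
  rk <- data.frame(feature = rownames(mat)[ord],
                   mean_abs_weight = score[ord],
                   n_neg = rowSums(mat < 0)[ord],
                   n_pos = rowSums(mat > 0)[ord],
                   all_negative = (rowSums(mat < 0) == ncol(mat))[ord],
                   rank = seq_along(ord),
                   row.names = NULL)
  list(ranking = rk, dominant = rk$feature[1], degenerate = all(score == 0))
}

#' Test weight differences between genders, feature by feature
#'
#' Two-tailed two-sample t-test per feature over the per-syllable weights of
#' the male vs. female matrices; reported uncorrected (mirroring the original
#' analysis choice) with a Holm-adjusted column alongside. Features whose
#' weights are constant in both genders are reported as missing.
#'
#' @param male,female 15 x 12 weight matrices.
#' @return data.frame: feature, t, df, p, p_holm.
#' @export
compare_lpc_across_gender <- function(male, female) {
  if (!identical(dim(male), dim(female))) stop("weight matrices differ in shape")
  stopifnot(identical(rownames(male), feature_names()))
  res <- lapply(feature_names(), function(f) {
    a <- male[f, ]; b <- female[f, ]
    if (stats::var(a) + stats::var(b) == 0) {
      # constant weights in both genders: no within-group variance, test undefined
      data.frame(feature = f, t = NA_real_, df = NA_real_, p = NA_real_)
    } else {
      tt <- stats::t.test(a, b)
      data.frame(feature = f, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Run the full marker-screening stage on a cohort
#'
#' Joins features and labels per (gender, syllable), trains the 24 linear SVMs,
#' assembles the per-gender weight matrices, and ranks the features over all
#' models.
#'
#' @param sessions feature table (from [simulate_cohort()] or [feature_table()]).
#' @param perception long perceptual record data.frame.
#' @param folds,cost,seed passed to [train_syllable_model()].
#' @param corpus syllable corpus.
#' @return list with `models` (gender -> syllable -> model), `lpc` (gender ->
#'   15 x 12 matrix), `ranking` (over both genders), `gender_comparison`.
#' @export
screen_markers <- function(sessions, perception, folds = 10, cost = 1, seed = 1L,
                           corpus = syllable_corpus()) {
  genders <- sort(unique(sessions$gender))
  models <- list(); lpc <- list()
  for (g in genders) models[[g]] <- list()
  for (s in corpus$syllable) {
    joined <- label_join(sessions, perception, s)
    for (g in genders) {
      if (is.null(joined[[g]])) next
      models[[g]][[s]] <- train_syllable_model(joined[[g]]$x, joined[[g]]$y,
                                               folds = folds, cost = cost,
                                               seed = seed, gender = g, syllable = s)
    }
  }
  for (g in genders) lpc[[g]] <- lpc_matrix(models[[g]], corpus)
  ranking <- rank_predictors(do.call(cbind, lpc))
  cmp <- if (all(c("male", "female") %in% genders))
    compare_lpc_across_gender(lpc$male, lpc$female) else NULL
  list(models = models, lpc = lpc, ranking = ranking, gender_comparison = cmp)
}
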