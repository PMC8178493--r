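#' ROC analysis of a scalar marker
#'
#' Builds the full ROC step curve of a score against binary labels (higher
#' score = more likely positive). The AUC is computed by trapezoidal
#' integration, which for a step curve equals the concordant-pair fraction with
#' half credit for ties; the 95% CI uses the Hanley-McNeil variance with a
#' normal approximation (DeLong variance available via `ci_method`). The
#' optimal cutoff maximizes Youden's J = sensitivity + specificity - 1 over
#' midpoints between adjacent distinct observed scores; J-ties are broken
#' toward higher specificity.
#'
#' @param scores numeric marker values.
#' @param labels 0/1 (or logical) class labels; 1 = positive.
#' @param ci_method "hanley-mcneil" (default) or "delong".
#' @param conf confidence level (default 0.95).
#' @return an object of class `roc_result`: `curve` (data.frame threshold /
#'   sensitivity / specificity), `auc`, `ci`, `se`, `cutoff`,
#'   `sensitivity`, `specificity` (at the cutoff), `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, ci_method = c("hanley-mcneil", "delong"),
                      conf = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for ROC analysis")

  thr <- sort(unique(scores))
  sens_ge <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec_ge <- vapply(thr, function(t) mean(neg < t), numeric(1))
  curve <- data.frame(threshold = c(-Inf, thr, Inf),
                      sensitivity = c(1, sens_ge, 0),
                      specificity = c(0, spec_ge, 1))
  # trapezoid over (FPR, TPR); FPR descends along the curve rows
  fpr <- 1 - curve$specificity; tpr <- curve$sensitivity
  auc <- sum((fpr[-nrow(curve)] - fpr[-1]) * (tpr[-nrow(curve)] + tpr[-1]) / 2)

  se <- switch(ci_method,
    "hanley-mcneil" = {
      q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
      sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
             (n0 * n1))
    },
    "delong" = {
      psi <- function(a, b) (a > b) + 0.5 * (a == b)
      v10 <- vapply(pos, function(a) mean(psi(a, neg)), numeric(1))
      v01 <- vapply(neg, function(b) mean(psi(pos, b)), numeric(1))
      sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
    })
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))

  # Youden-optimal cutoff over midpoints between adjacent distinct scores
  mids <- if (length(thr) > 1) (thr[-length(thr)] + thr[-1]) / 2 else thr
  sens_m <- vapply(mids, function(t) mean(pos > t), numeric(1))
  spec_m <- vapply(mids, function(t) mean(neg <= t), numeric(1))
  j <- sens_m + spec_m - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-spec_m[best], -mids[best])][1]
  structure(list(curve = curve, auc = auc, se = se, ci = ci,
                 ci_method = ci_method, cutoff = mids[best],
                 sensitivity = sens_m[best], specificity = spec_m[best],
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.3f (95%% CI %.3f-%.3f, %s), cutoff = %.3f, sens = %.1f%%, spec = %.1f%%, n = %d+/%d->\n",
              x$auc, x$ci[1], x$ci[2], x$ci_method, x$cutoff,
              100 * x$sensitivity, 100 * x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Stage-discrimination ROC analyses of a marker
#'
#' Runs the two diagnostic dichotomies on pre-operative sessions: advanced
#' disease (T3-4 positive vs. T0-2) and any disease (T1-4 positive vs. healthy
#' T0 controls).
#'
#' @param sessions feature table with `timepoint`, `tclass` and the marker
#'   column.
#' @param marker marker column name (default "FCR").
#' @param ... passed to [roc_curve()].
#' @return list with elements `t34_vs_t02` and `t14_vs_t0`, each a `roc_result`.
#' @export
stage_rocs <- function(sessions, marker = "FCR", ...) {
  pre <- sessions[sessions$timepoint == "pre" & !is.na(sessions[[marker]]), ]
  if (nrow(pre) == 0) stop("no pre-operative sessions with marker values")
  mk <- pre[[marker]]
  run <- function(pos_lab, what) {
    if (sum(pos_lab) == 0 || sum(!pos_lab) == 0)
      stop("empty group side for dichotomy ", what)
    roc_curve(mk, as.integer(pos_lab), ...)
  }
  list(t34_vs_t02 = run(pre$tclass >= 3, "T3-4 vs T0-2"),
       t14_vs_t0 = run(pre$tclass >= 1, "T1-4 vs T0"))
}
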