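# Shared fixtures and brute-force oracles used across test files.

# The worked reference profile: /i/(270, 2290), /u/(300, 870), /a/(730, 1090).
reference_profile <- function() {
  formant_profile("ref", "male", "pre",
                  rbind(A = c(730, 1090), I = c(270, 2290), U = c(300, 870)))
}

# Brute-force two-sided Fisher exact p for a 2x2 table: enumerate every table
# with the observed margins and sum the hypergeometric probabilities of all
# tables no more probable than the observed one.
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_range, function(a)
    stats::dhyper(a, c1, n - c1, r1), numeric(1))
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force AUC: concordant-pair fraction with half credit for ties.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# A small feature matrix with canonical names: FCR carries the signal, the
# other 14 columns are independent noise.
planted_fcr_data <- function(n = 200, seed = 42, threshold = 0.95) {
  set.seed(seed)
  x <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, feature_names()))
  x[, "FCR"] <- runif(n, 0.8, 1.1)
  y <- as.integer(x[, "FCR"] < threshold)
  list(x = x, y = y)
}
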