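# Independent oracles used across test files.

# Clopper-Pearson by direct bisection of the binomial tail probabilities,
# independent of the beta-quantile implementation.
bisect_clopper_pearson <- function(k, n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p, lower.tail = FALSE) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# AUC by brute-force pair counting (Mann-Whitney, ties half)
pairwise_auc <- function(score, truth) {
  pos <- score[truth == "positive"]
  neg <- score[truth == "negative"]
  mean(outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y)))
}

# random ordinal score/truth instance with both classes present
random_score_instance <- function(max_n = 30) {
  npos <- sample(2:max_n, 1)
  nneg <- sample(2:max_n, 1)
  list(score = c(sample(0:5, npos, TRUE), sample(0:5, nneg, TRUE)),
       truth = rep(c("positive", "negative"), c(npos, nneg)))
}

# a small hand-built cohort wrapper
quick_patient <- function(id, ct_call = "negative", ct_lesions = no_lesions(),
                          pet_call = "negative", pet_lesions = no_lesions(),
                          ...) {
  patient_record(id, risk_factors = "bilateral_nodes",
                 primary_site = "oropharynx",
                 ct = modality_reading(ct_call, ct_lesions, "ct"),
                 pet = modality_reading(pet_call, pet_lesions, "pet"),
                 ...)
}
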