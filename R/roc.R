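# ROC analysis over five-point ordinal reader scores.
#
# The empirical curve is evaluated at thresholds "score >= t" for t = 0..6
# (t = 0 calls everyone positive, t = 6 no one).  The area under the
# trapezoidal curve equals the two-sample Mann-Whitney statistic with ties
# counted half.  Inference uses the paired placement-value (DeLong-type)
# variance/covariance estimator, which supports both the test against the
# null AUC of 0.5 and the paired comparison of two modalities read on the
# same patients.

#' Per-patient ordinal score and truth for one modality
#'
#' The patient-level score is the Likert score of the most suspicious lesion
#' on that modality (0 when no lesion was scored).
#'
#' @param set a `dm_analysis_set` or a `dm_cohort`.
#' @param modality `"ct"` or `"pet"`.
#' @return data.frame: `patient_id`, `score` (ordinal 0--5), `truth`.
#' @export
patient_scores <- function(set, modality = c("ct", "pet")) {
  modality <- match.arg(modality)
  cohort <- if (inherits(set, "dm_analysis_set")) set$patients else set
  data.frame(patient_id = cohort$patient_id,
             score = cohort[[paste0(modality, "_likert_max")]],
             truth = dm_truth(cohort),
             stringsAsFactors = FALSE)
}

.check_scores <- function(score, truth, who = "empirical_roc") {
  if (length(score) != length(truth))
    stop(who, ": score and truth must be the same length", call. = FALSE)
  stopifnot(all(truth %in% .dm_calls))
  if (!any(truth == "positive") || !any(truth == "negative"))
    stop(who, ": degenerate truth (need at least one positive and one ",
         "negative patient)", call. = FALSE)
}

#' Empirical ROC curve and AUC over ordinal scores
#'
#' @param score per-patient ordinal scores 0--5 (any ordered numeric works).
#' @param truth per-patient `"positive"`/`"negative"` reference truth.
#' @param thresholds thresholds at which "score >= t" defines a positive
#'   call; default 0:6 for the five-point scale with its 0 sentinel.
#' @return A list of class `dm_roc`: `operating_points` (threshold,
#'   sensitivity, specificity), `auc` (trapezoidal), `auc_se` (placement
#'   value standard error), `p_vs_half` (two-sided normal test of the null
#'   AUC = 0.5), `q_point` (see [q_point()]), `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(score, truth, thresholds = 0:6) {
  .check_scores(score, truth)
  pos <- score[truth == "positive"]
  neg <- score[truth == "negative"]
  sens <- vapply(thresholds, function(t) mean(pos >= t), 0)
  spec <- vapply(thresholds, function(t) mean(neg < t), 0)
  pts <- data.frame(threshold = thresholds, sensitivity = sens,
                    specificity = spec)
  # trapezoid over (FPR, TPR), traversed from the all-positive corner
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pl <- .placements(pos, neg)
  se <- sqrt(stats::var(pl$v10) / length(pos) +
             stats::var(pl$v01) / length(neg))
  p <- if (se == 0) as.numeric(auc == 0.5) else
    2 * stats::pnorm(-abs(auc - 0.5) / se)
  res <- structure(list(operating_points = pts, auc = auc, auc_se = se,
                        p_vs_half = p, n_pos = length(pos),
                        n_neg = length(neg)),
                   class = "dm_roc")
  res$q_point <- q_point(res)
  res
}

# Placement values: v10[i] = fraction of negatives below positive i (ties
# half); v01[j] = fraction of positives above negative j.  mean(v10) =
# mean(v01) = AUC.
.placements <- function(pos, neg) {
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01)
}

#' @export
print.dm_roc <- function(x, ...) {
  cat("<dm_roc> AUC = ", format(x$auc, digits = 3), " (SE ",
      format(x$auc_se, digits = 3), "), p vs 0.5 = ",
      format(x$p_vs_half, digits = 3), "; Q-point at score >= ",
      x$q_point$threshold, " (sens ",
      format(x$q_point$sensitivity, digits = 3), ", spec ",
      format(x$q_point$specificity, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.dm_roc <- function(x, add = FALSE, col = "black", ...) {
  pts <- x$operating_points
  fpr <- rev(1 - pts$specificity); tpr <- rev(pts$sensitivity)
  if (!add) {
    plot(fpr, tpr, type = "b", col = col, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "Sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else {
    graphics::lines(fpr, tpr, type = "b", col = col, ...)
  }
  invisible(x)
}

#' Q-point of an ROC curve
#'
#' The operating point jointly optimising sensitivity and specificity,
#' implemented as the maximiser of Youden's J = sensitivity + specificity - 1.
#' Ties are broken toward higher sensitivity (the lower threshold): in a
#' screening setting a missed metastasis costs more than a work-up of a
#' false positive.
#'
#' @param roc a `dm_roc` from [empirical_roc()].
#' @return list(`threshold`, `sensitivity`, `specificity`).
#' @export
q_point <- function(roc) {
  pts <- roc$operating_points
  j <- pts$sensitivity + pts$specificity - 1
  # order: best J first, then higher sensitivity
  best <- order(-j, -pts$sensitivity)[1]
  list(threshold = pts$threshold[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best])
}

#' Paired AUC inference for two modalities read on the same patients
#'
#' Variance and covariance of the two empirical AUCs by the paired
#' placement-value (DeLong-type) estimator; two-sided normal tests of each
#' AUC against the null value 0.5 and of the difference between the AUCs.
#'
#' @param score_a,score_b per-patient ordinal scores for the two modalities,
#'   aligned to the same patients (paired design).
#' @param truth shared `"positive"`/`"negative"` truth vector.
#' @return list: `auc_a`, `auc_b`, `se_a`, `se_b`, `cov_ab`, `diff`,
#'   `se_diff`, `p_a_vs_half`, `p_b_vs_half`, `p_a_vs_b`.
#' @export
auc_inference <- function(score_a, score_b, truth) {
  if (length(score_a) != length(score_b))
    stop("auc_inference: unpaired inputs (score vectors differ in length)",
         call. = FALSE)
  .check_scores(score_a, truth, "auc_inference")
  .check_scores(score_b, truth, "auc_inference")
  ispos <- truth == "positive"
  pa <- .placements(score_a[ispos], score_a[!ispos])
  pb <- .placements(score_b[ispos], score_b[!ispos])
  m <- sum(ispos); n <- sum(!ispos)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  var_a <- stats::var(pa$v10) / m + stats::var(pa$v01) / n
  var_b <- stats::var(pb$v10) / m + stats::var(pb$v01) / n
  cov_ab <- stats::cov(pa$v10, pb$v10) / m + stats::cov(pa$v01, pb$v01) / n
  ztest <- function(delta, v) {
    if (abs(delta) < .Machine$double.eps^0.5) return(1)
    if (v <= 0) return(0)
    2 * stats::pnorm(-abs(delta) / sqrt(v))
  }
  var_diff <- var_a + var_b - 2 * cov_ab
  list(auc_a = auc_a, auc_b = auc_b,
       se_a = sqrt(var_a), se_b = sqrt(var_b), cov_ab = cov_ab,
       diff = auc_a - auc_b, se_diff = sqrt(max(var_diff, 0)),
       p_a_vs_half = ztest(auc_a - 0.5, var_a),
       p_b_vs_half = ztest(auc_b - 0.5, var_b),
       p_a_vs_b = ztest(auc_a - auc_b, var_diff))
}
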