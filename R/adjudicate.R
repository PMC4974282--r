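# Reference-standard adjudication.
#
# Truth is defined by the diagnostic work-up at screening plus 12 months of
# clinical follow-up: a patient is truth-positive for distant metastases if
# metastases were established at screening or manifested within the window.
# Patients who develop a second primary tumor during follow-up together with
# distant lesions are excluded from accuracy analysis: imaging cannot tell
# whether those lesions arose from the index tumor or from the new primary.
# A further stratification retains only patients with locoregional control,
# since metastases appearing after a locoregional recurrence may have been
# reseeded rather than missed by screening.

#' Reference-standard truth for distant metastases
#'
#' @param outcome a cohort (or any data.frame carrying the outcome flag
#'   columns `dm_at_screening` and `dm_within_12mo`).
#' @return Character vector, `"positive"` when metastases were established at
#'   screening or within 12-month follow-up, `"negative"` otherwise.
#' @export
dm_truth <- function(outcome) {
  stopifnot(all(c("dm_at_screening", "dm_within_12mo") %in% names(outcome)))
  ifelse(outcome$dm_at_screening | outcome$dm_within_12mo,
         "positive", "negative")
}

#' Classify a screening call against the reference standard
#'
#' @param call,truth equal-length vectors of `"positive"`/`"negative"`.
#' @return Character vector in `{"TP","FP","FN","TN"}`.
#' @export
adjudicate <- function(call, truth) {
  if (length(call) != length(truth))
    stop("adjudicate: call and truth must be the same length", call. = FALSE)
  stopifnot(all(call %in% .dm_calls), all(truth %in% .dm_calls))
  ifelse(call == "positive",
         ifelse(truth == "positive", "TP", "FP"),
         ifelse(truth == "positive", "FN", "TN"))
}

.new_analysis_set <- function(label, patients, excluded) {
  structure(list(label = label, patients = patients, excluded = excluded),
            class = "dm_analysis_set")
}

#' @export
print.dm_analysis_set <- function(x, ...) {
  cat("<dm_analysis_set> '", x$label, "': ", nrow(x$patients), " patients",
      sep = "")
  if (nrow(x$excluded)) cat(" (", nrow(x$excluded), " excluded)", sep = "")
  cat("\n")
  invisible(x)
}

#' Evaluable analysis set
#'
#' Excludes patients whose distant lesions are of ambiguous origin: those who
#' developed a second primary tumor during follow-up while also being
#' truth-positive for distant metastases.  Each exclusion is recorded with
#' its reason.
#'
#' @param cohort a `dm_cohort`.
#' @return A `dm_analysis_set` with `label = "evaluable"`, the retained
#'   `patients`, and an `excluded` data.frame (`patient_id`, `reason`).
#' @export
evaluable_set <- function(cohort) {
  validate_cohort(cohort)
  ambiguous <- cohort$spt_within_12mo & dm_truth(cohort) == "positive"
  excluded <- data.frame(
    patient_id = cohort$patient_id[ambiguous],
    reason = rep("metastasis origin ambiguous: second primary tumor during follow-up",
                 sum(ambiguous)),
    stringsAsFactors = FALSE)
  .new_analysis_set("evaluable", cohort[!ambiguous, , drop = FALSE], excluded)
}

#' Locoregional-control analysis set
#'
#' From the evaluable set, retains only patients with locoregional control
#' during follow-up.
#'
#' @param evaluable a `dm_analysis_set` produced by [evaluable_set()].
#' @return A `dm_analysis_set` with `label = "lrc"`; the `excluded` log
#'   carries both the upstream exclusions and the stratification removals.
#' @export
locoregional_set <- function(evaluable) {
  if (!inherits(evaluable, "dm_analysis_set") || evaluable$label != "evaluable")
    stop("locoregional_set: input must be the evaluable analysis set",
         call. = FALSE)
  p <- evaluable$patients
  keep <- p$locoregional_control
  removed <- data.frame(patient_id = p$patient_id[!keep],
                        reason = rep("no locoregional control during follow-up",
                                     sum(!keep)),
                        stringsAsFactors = FALSE)
  .new_analysis_set("lrc", p[keep, , drop = FALSE],
                    rbind(evaluable$excluded, removed))
}

#' Select an analysis set by label
#'
#' @param cohort a `dm_cohort`.
#' @param set `"all"` (every screened patient), `"evaluable"` (ambiguous
#'   metastasis origins excluded) or `"lrc"` (evaluable patients with
#'   locoregional control).
#' @return A `dm_analysis_set`.
#' @export
analysis_set <- function(cohort, set = c("evaluable", "all", "lrc")) {
  set <- match.arg(set)
  switch(set,
         all = .new_analysis_set("all", cohort,
                                 data.frame(patient_id = character(),
                                            reason = character(),
                                            stringsAsFactors = FALSE)),
         evaluable = evaluable_set(cohort),
         lrc = locoregional_set(evaluable_set(cohort)))
}
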