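# End-to-end runs: read -> adjudicate -> stratify -> combine -> tabulate ->
# render, with machine-readable JSON, a plain-text table and a per-patient
# audit trail.  Report files carry no timestamps, so identical input and
# configuration produce byte-identical output.

.profile_json <- function(profile) {
  lapply(seq_len(nrow(profile)), function(i) {
    r <- profile[i, ]
    list(metric = r$metric, numerator = r$numerator,
         denominator = r$denominator,
         point = if (is.na(r$point)) NULL else r$point,
         ci_low = if (is.na(r$ci_low)) NULL else r$ci_low,
         ci_high = if (is.na(r$ci_high)) NULL else r$ci_high,
         percent = if (is.na(r$point)) NULL else percent_half_up(r$point))
  })
}

#' Run the accuracy pipeline on a cohort
#'
#' Applies the reference-standard adjudication, the requested analysis-set
#' selection, the combined PET/CT interpretation rule, and the accuracy
#' statistics, for CT, PET and the combination.
#'
#' @param input a `dm_cohort`, or a path to a cohort file readable by
#'   [read_cohort()].
#' @param set analysis set selector: `"all"`, `"evaluable"` or `"lrc"`.
#' @param confidence confidence level for the exact intervals.
#' @param out_dir optional directory; when given, writes `accuracy.txt`
#'   (rendered table), `accuracy.json` (per-cell numerator/denominator/
#'   point/bounds), `audit.csv` (per-patient calls, rule fired, truth and
#'   TP/FP/FN/TN class per method) and `exclusions.csv`.
#' @param format passed to [read_cohort()] when `input` is a path.
#' @return Invisibly, a list: `set` (the analysis set), `tables`,
#'   `profiles`, `rendered` (text lines), `audit` (data.frame).
#' @export
run_accuracy <- function(input, set = c("evaluable", "all", "lrc"),
                         confidence = 0.95, out_dir = NULL,
                         format = c("auto", "csv", "json")) {
  set <- match.arg(set)
  stopifnot(confidence > 0, confidence < 1)
  cohort <- if (inherits(input, "dm_cohort")) input
            else read_cohort(input, match.arg(format))
  aset <- analysis_set(cohort, set)
  patients <- aset$patients
  if (nrow(patients) == 0L)
    stop("run_accuracy: analysis set '", set, "' is empty", call. = FALSE)
  truth <- dm_truth(patients)
  comb <- combined_calls(patients)
  calls <- list(`CT` = patients$ct_call, `PET` = patients$pet_call,
                `PET and CT` = comb$combined_call)
  tables <- lapply(calls, build_table, truths = truth)
  profiles <- lapply(tables, accuracy_profile, conf = confidence)
  n_label <- sprintf("n = %d patients, set = %s", nrow(patients), set)
  rendered <- render_table(profiles, n_label)
  audit <- data.frame(patient_id = patients$patient_id,
                      ct_call = patients$ct_call,
                      pet_call = patients$pet_call,
                      combined_call = comb$combined_call,
                      rule_fired = comb$rule_fired,
                      truth = truth,
                      class_ct = adjudicate(patients$ct_call, truth),
                      class_pet = adjudicate(patients$pet_call, truth),
                      class_combined = adjudicate(comb$combined_call, truth),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(rendered, file.path(out_dir, "accuracy.txt"))
    jsonlite::write_json(
      list(analysis_set = set, n = nrow(patients), confidence = confidence,
           methods = lapply(profiles, .profile_json),
           tables = lapply(tables, unclass)),
      file.path(out_dir, "accuracy.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(audit, file.path(out_dir, "audit.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(aset$excluded, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(set = aset, tables = tables, profiles = profiles,
                 rendered = rendered, audit = audit))
}

#' Run the ROC pipeline on a cohort
#'
#' Empirical ROC curve, trapezoidal AUC, Q-point and paired placement-value
#' inference over the per-patient ordinal scores of both modalities.
#'
#' @inheritParams run_accuracy
#' @param out_dir optional directory; writes `roc.json`.
#' @return Invisibly, a list: `ct`, `pet` (each a `dm_roc`), `inference`
#'   (paired AUC comparison, [auc_inference()]).
#' @export
run_roc <- function(input, set = c("evaluable", "all", "lrc"),
                    out_dir = NULL, format = c("auto", "csv", "json")) {
  set <- match.arg(set)
  cohort <- if (inherits(input, "dm_cohort")) input
            else read_cohort(input, match.arg(format))
  aset <- analysis_set(cohort, set)
  sc_ct <- patient_scores(aset, "ct")
  sc_pet <- patient_scores(aset, "pet")
  if (length(unique(sc_ct$truth)) < 2L)
    stop("run_roc: analysis set '", set,
         "' has only one truth class; ROC is undefined", call. = FALSE)
  roc_ct <- empirical_roc(sc_ct$score, sc_ct$truth)
  roc_pet <- empirical_roc(sc_pet$score, sc_pet$truth)
  inference <- auc_inference(sc_ct$score, sc_pet$score, sc_ct$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    roc_json <- function(r) list(operating_points = r$operating_points,
                                 auc = r$auc, auc_se = r$auc_se,
                                 p_vs_half = r$p_vs_half, q_point = r$q_point)
    jsonlite::write_json(
      list(analysis_set = set, n = nrow(aset$patients),
           ct = roc_json(roc_ct), pet = roc_json(roc_pet),
           comparison = inference),
      file.path(out_dir, "roc.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
  }
  invisible(list(ct = roc_ct, pet = roc_pet, inference = inference))
}
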