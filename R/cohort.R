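#' dmscreen: combined PET/CT interpretation for distant-metastasis screening
#'
#' Evaluates screening for distant metastases in head and neck squamous cell
#' carcinoma (HNSCC) patients with high-risk factors, where each patient has a
#' paired whole-body FDG-PET and contrast-enhanced chest CT reading.  The
#' package provides the combined interpretation rule ([classify_pair()]),
#' follow-up-based reference-standard adjudication ([dm_truth()],
#' [evaluable_set()], [locoregional_set()]), diagnostic accuracy statistics
#' with exact confidence intervals ([accuracy_profile()], [clopper_pearson()]),
#' ROC analysis over ordinal reader scores ([empirical_roc()],
#' [auc_inference()]), a deterministic 47-patient reference cohort
#' ([build_paper_fixture()]) and a cohort simulator ([simulate_cohort()]).
#'
#' @name dmscreen-package
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Domain vocabulary (single source of truth for enumerations)

.dm_calls        <- c("positive", "negative")
.dm_locations    <- c("lung", "extra_pulmonary")
.dm_confirmation <- c("histopathology", "progression", "none")
.dm_risk_factors <- c("ge3_nodes", "bilateral_nodes", "node_ge6cm",
                      "low_jugular", "recurrence", "second_primary")

.cohort_columns <- c("patient_id", "risk_factors", "primary_site",
                     "ct_call", "ct_likert_max", "ct_lesions",
                     "pet_call", "pet_likert_max", "pet_lesions",
                     "dm_at_screening", "spt_at_screening",
                     "dm_within_12mo", "spt_within_12mo",
                     "locoregional_control", "confirmation")

#' Construct a lesion table
#'
#' One row per lesion found on a single modality.  `size_mm` is recorded only
#' for CT findings (PET localises but does not size lesions here); a missing
#' size is `NA`, never 0.  `likert` is the five-point ordinal suspicion score
#' for distant metastasis (1 = definitely benign ... 5 = definitely
#' malignant), with 0 as the below-scale sentinel for a lesion that is not
#' suspicious for distant metastasis at all (e.g. an imaged second primary
#' tumor).
#'
#' @param location `"lung"` or `"extra_pulmonary"`, recycled.
#' @param size_mm positive diameter in millimetres, or `NA` when not sized.
#' @param multiple logical; is the lesion part of a multi-lesion pattern?
#' @param likert integer 0--5.
#' @return A `data.frame` with columns `location`, `size_mm`, `multiple`,
#'   `likert`; zero rows for `no_lesions()`.
#' @examples
#' lesion_set("lung", size_mm = c(4, 7), multiple = TRUE, likert = c(4, 3))
#' @export
lesion_set <- function(location = character(), size_mm = NA_real_,
                       multiple = FALSE, likert = integer()) {
  n <- max(length(location), length(likert))
  df <- data.frame(location = rep_len(as.character(location), n),
                   size_mm  = rep_len(as.numeric(size_mm), n),
                   multiple = rep_len(as.logical(multiple), n),
                   likert   = rep_len(as.integer(likert), n),
                   stringsAsFactors = FALSE)
  validate_lesions(df)
  df
}

#' @rdname lesion_set
#' @export
no_lesions <- function() {
  data.frame(location = character(), size_mm = numeric(),
             multiple = logical(), likert = integer(),
             stringsAsFactors = FALSE)
}

validate_lesions <- function(df, where = "lesion") {
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(invisible(df))
  if (!all(df$location %in% .dm_locations))
    stop(where, ": location must be one of ",
         paste(.dm_locations, collapse = ", "), call. = FALSE)
  if (!all(df$likert %in% 0:5))
    stop(where, ": likert score out of range 0-5 (got ",
         paste(df$likert[!df$likert %in% 0:5], collapse = ", "), ")",
         call. = FALSE)
  sized <- !is.na(df$size_mm)
  if (any(df$size_mm[sized] <= 0))
    stop(where, ": size_mm must be strictly positive when present",
         call. = FALSE)
  if (any(sized & df$location == "extra_pulmonary" & FALSE))
    stop(where, ": internal", call. = FALSE)
  invisible(df)
}

#' Construct a single-modality reading
#'
#' Bundles the clinical report's binary call for distant metastases with the
#' per-lesion detail.  The derived `likert_max` (the score of the most
#' suspicious lesion, 0 when there are none) is the patient-level ordinal
#' score used for ROC analysis.
#'
#' @param call `"positive"` or `"negative"` -- the report's call for distant
#'   metastases.
#' @param lesions a lesion table from [lesion_set()]; defaults to none.
#' @param modality `"ct"` or `"pet"`; CT findings may carry sizes, PET
#'   findings may not.
#' @return A list with class `dm_reading`: `call`, `lesions`, `likert_max`.
#' @export
modality_reading <- function(call, lesions = no_lesions(),
                             modality = c("ct", "pet")) {
  modality <- match.arg(modality)
  call <- match.arg(call, .dm_calls)
  validate_lesions(lesions, where = paste0(modality, " lesion"))
  if (modality == "pet" && any(!is.na(lesions$size_mm)))
    stop("pet lesion: size_mm is recorded for CT findings only", call. = FALSE)
  structure(list(call = call, lesions = lesions,
                 likert_max = likert_max(lesions), modality = modality),
            class = "dm_reading")
}

#' @rdname modality_reading
#' @param lesions a lesion table.
#' @export
likert_max <- function(lesions) {
  if (nrow(lesions) == 0L) 0L else max(lesions$likert)
}

#' Assemble a patient record
#'
#' @param patient_id unique identifier.
#' @param risk_factors character vector of high-risk factors (non-empty;
#'   eligibility requires at least one), drawn from `"ge3_nodes"`,
#'   `"bilateral_nodes"`, `"node_ge6cm"`, `"low_jugular"`, `"recurrence"`,
#'   `"second_primary"`.
#' @param primary_site free-text site label (synchronous tumors joined with
#'   `"+"`).
#' @param ct,pet [modality_reading()] objects.
#' @param dm_at_screening,spt_at_screening,dm_within_12mo,spt_within_12mo,locoregional_control
#'   outcome flags (logical).  Flags are not mutually exclusive.
#' @param confirmation `"histopathology"`, `"progression"` or `"none"`.
#' @return One-row cohort data.frame.
#' @export
patient_record <- function(patient_id, risk_factors, primary_site,
                           ct, pet,
                           dm_at_screening = FALSE, spt_at_screening = FALSE,
                           dm_within_12mo = FALSE, spt_within_12mo = FALSE,
                           locoregional_control = TRUE,
                           confirmation = "none") {
  stopifnot(inherits(ct, "dm_reading"), inherits(pet, "dm_reading"))
  df <- data.frame(patient_id = as.character(patient_id),
                   primary_site = as.character(primary_site),
                   ct_call = ct$call, ct_likert_max = ct$likert_max,
                   pet_call = pet$call, pet_likert_max = pet$likert_max,
                   dm_at_screening = dm_at_screening,
                   spt_at_screening = spt_at_screening,
                   dm_within_12mo = dm_within_12mo,
                   spt_within_12mo = spt_within_12mo,
                   locoregional_control = locoregional_control,
                   confirmation = confirmation,
                   stringsAsFactors = FALSE)
  df$risk_factors <- list(as.character(risk_factors))
  df$ct_lesions <- list(ct$lesions)
  df$pet_lesions <- list(pet$lesions)
  df[, .cohort_columns]
}

#' Build and validate a screening cohort
#'
#' A cohort is a data.frame with one row per screened patient, list-columns
#' for risk factors and per-modality lesion tables, and class `dm_cohort`.
#'
#' @param records a data.frame of patient rows (e.g. `rbind` of
#'   [patient_record()] output) or a list of such one-row frames.
#' @return The validated cohort, classed `dm_cohort`.
#' @export
as_cohort <- function(records) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  cohort <- records[, .cohort_columns]
  class(cohort) <- c("dm_cohort", "data.frame")
  validate_cohort(cohort)
  cohort
}

#' @rdname as_cohort
#' @param cohort a cohort to validate; invariants checked: unique patient
#'   ids, valid enumerations, likert within 0--5, positive sizes (CT only),
#'   `likert_max` consistent with the lesion tables, non-empty risk factors.
#' @export
validate_cohort <- function(cohort) {
  if (anyDuplicated(cohort$patient_id))
    stop("cohort: duplicated patient_id", call. = FALSE)
  bad_call <- !(cohort$ct_call %in% .dm_calls) | !(cohort$pet_call %in% .dm_calls)
  if (any(bad_call))
    stop("cohort: invalid call for patient ",
         paste(cohort$patient_id[bad_call], collapse = ", "), call. = FALSE)
  if (!all(cohort$confirmation %in% .dm_confirmation))
    stop("cohort: invalid confirmation value", call. = FALSE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$patient_id[i]
    if (length(cohort$risk_factors[[i]]) == 0L)
      stop("cohort: patient ", id, " has no risk factors ",
           "(eligibility requires at least one)", call. = FALSE)
    ctl <- cohort$ct_lesions[[i]]
    petl <- cohort$pet_lesions[[i]]
    validate_lesions(ctl, where = paste0("patient ", id, " ct lesion"))
    validate_lesions(petl, where = paste0("patient ", id, " pet lesion"))
    if (any(!is.na(petl$size_mm)))
      stop("cohort: patient ", id,
           ": PET lesions must not carry sizes", call. = FALSE)
    if (cohort$ct_likert_max[i] != likert_max(ctl) ||
        cohort$pet_likert_max[i] != likert_max(petl))
      stop("cohort: patient ", id, ": likert_max inconsistent with lesions",
           call. = FALSE)
  }
  flags <- c("dm_at_screening", "spt_at_screening", "dm_within_12mo",
             "spt_within_12mo", "locoregional_control")
  for (f in flags)
    if (!is.logical(cohort[[f]]) || anyNA(cohort[[f]]))
      stop("cohort: column ", f, " must be logical without NA", call. = FALSE)
  invisible(cohort)
}

#' @export
print.dm_cohort <- function(x, ...) {
  cat("<dm_cohort> ", nrow(x), " patients; ",
      sum(x$dm_at_screening | x$dm_within_12mo), " with distant metastases, ",
      sum(x$spt_at_screening | x$spt_within_12mo),
      " with second primary tumors\n", sep = "")
  invisible(x)
}
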