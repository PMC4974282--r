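# Combined PET/CT interpretation rule.
#
# A single positive/negative call for distant metastases from the paired
# modality calls.  PET positivity dominates unconditionally: any FDG-avid
# lesion is treated as malignant regardless of the CT interpretation.  When
# only CT is positive, the decision follows lesion size relative to the 5-mm
# PET detection limit: a suspicious lesion strictly below 5 mm is invisible
# to PET, so PET's negativity carries no information and the CT call stands;
# at or above 5 mm a PET-negative lesion is discounted as benign.

.dm_rules <- c("both_positive", "pet_only_positive", "ct_small_lesion",
               "ct_large_lesion_discounted", "both_negative")

#' Combined interpretation of one PET/CT call pair
#'
#' @param pet_call,ct_call `"positive"` or `"negative"` -- the per-modality
#'   clinical calls for distant metastases.
#' @param smallest_suspicious_ct_size_mm diameter (mm) of the smallest
#'   suspicious CT lesion; required when `ct_call` is positive, `NA`
#'   otherwise.  The smallest lesion drives the size branch because any
#'   sub-threshold lesion is by construction invisible to PET.
#' @param size_cutoff_mm PET detection limit; lesions strictly below it are
#'   called on CT alone.  Default 5 mm.
#' @return A list of class `dm_combined_call` with elements `call`
#'   (`"positive"`/`"negative"`) and `rule_fired` (one of `"both_positive"`,
#'   `"pet_only_positive"`, `"ct_small_lesion"`,
#'   `"ct_large_lesion_discounted"`, `"both_negative"`).  Exactly one rule
#'   fires per classification.
#' @examples
#' classify_pair("negative", "positive", 4)   # sub-limit lesion: positive
#' classify_pair("negative", "positive", 15)  # PET discounts it: negative
#' classify_pair("positive", "negative")      # PET dominates: positive
#' @export
classify_pair <- function(pet_call, ct_call,
                          smallest_suspicious_ct_size_mm = NA_real_,
                          size_cutoff_mm = 5) {
  pet_call <- match.arg(pet_call, .dm_calls)
  ct_call <- match.arg(ct_call, .dm_calls)
  size <- as.numeric(smallest_suspicious_ct_size_mm)
  if (ct_call == "positive" && is.na(size))
    stop("classify_pair: ct_call is positive but no suspicious lesion size ",
         "was supplied; the size branch cannot be evaluated", call. = FALSE)
  if (!is.na(size) && size <= 0)
    stop("classify_pair: lesion size must be positive", call. = FALSE)
  if (pet_call == "positive") {
    rule <- if (ct_call == "positive") "both_positive" else "pet_only_positive"
    call <- "positive"
  } else if (ct_call == "positive") {
    if (size < size_cutoff_mm) {
      rule <- "ct_small_lesion"; call <- "positive"
    } else {
      rule <- "ct_large_lesion_discounted"; call <- "negative"
    }
  } else {
    rule <- "both_negative"; call <- "negative"
  }
  structure(list(call = call, rule_fired = rule), class = "dm_combined_call")
}

#' @export
print.dm_combined_call <- function(x, ...) {
  cat("<dm_combined_call> ", x$call, " (", x$rule_fired, ")\n", sep = "")
  invisible(x)
}

#' Combined interpretation of one patient's paired readings
#'
#' Extracts the binary calls from the two [modality_reading()]s and, when CT
#' is positive, the minimum size among the CT lesions, then delegates to
#' [classify_pair()].  Likert scores are not consulted: the combined reading
#' is scored from the binary clinical reports, as in the validation study;
#' the ordinal scores feed only the ROC analysis.
#'
#' @param ct,pet [modality_reading()] objects.
#' @inheritParams classify_pair
#' @return A `dm_combined_call`.
#' @export
classify_patient <- function(ct, pet, size_cutoff_mm = 5) {
  stopifnot(inherits(ct, "dm_reading"), inherits(pet, "dm_reading"))
  classify_pair(pet$call, ct$call, .min_ct_size(ct$call, ct$lesions),
                size_cutoff_mm = size_cutoff_mm)
}

.min_ct_size <- function(ct_call, lesions) {
  if (ct_call != "positive") return(NA_real_)
  sizes <- lesions$size_mm[!is.na(lesions$size_mm)]
  if (length(sizes) == 0L) NA_real_ else min(sizes)
}

#' Combined calls for every patient in a cohort
#'
#' @param cohort a `dm_cohort` (or the `patients` of an analysis set).
#' @inheritParams classify_pair
#' @return A data.frame with one row per patient: `patient_id`, `ct_call`,
#'   `pet_call`, `min_ct_size_mm`, `combined_call`, `rule_fired`.
#' @export
combined_calls <- function(cohort, size_cutoff_mm = 5) {
  n <- nrow(cohort)
  call <- character(n); rule <- character(n); size <- numeric(n)
  for (i in seq_len(n)) {
    size[i] <- .min_ct_size(cohort$ct_call[i], cohort$ct_lesions[[i]])
    cc <- classify_pair(cohort$pet_call[i], cohort$ct_call[i], size[i],
                        size_cutoff_mm = size_cutoff_mm)
    call[i] <- cc$call; rule[i] <- cc$rule_fired
  }
  data.frame(patient_id = cohort$patient_id,
             ct_call = cohort$ct_call, pet_call = cohort$pet_call,
             min_ct_size_mm = size,
             combined_call = call, rule_fired = rule,
             stringsAsFactors = FALSE)
}
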