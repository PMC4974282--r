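# Tabular cohort I/O.
#
# CSV: one row per patient, fixed header; risk factors semicolon-delimited;
# lesions packed as semicolon-delimited "location:size_mm:multiple:likert"
# specs with an empty size field (never 0) for unsized findings; booleans 0/1.
# JSON: the same schema with nested lesion objects.

.pack_lesions <- function(df) {
  if (nrow(df) == 0L) return("")
  size <- ifelse(is.na(df$size_mm), "", as.character(df$size_mm))
  paste(paste(df$location, size, as.integer(df$multiple), df$likert,
              sep = ":"), collapse = ";")
}

.unpack_lesions <- function(s, row, col) {
  if (is.na(s) || !nzchar(s)) return(no_lesions())
  specs <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- strsplit(specs, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("row ", row, ", column ", col, ": malformed lesion spec '",
         specs[bad][1], "' (expected location:size_mm:multiple:likert)",
         call. = FALSE)
  m <- do.call(rbind, parts)
  size <- suppressWarnings(as.numeric(m[, 2]))
  size[!nzchar(m[, 2])] <- NA_real_
  if (any(nzchar(m[, 2]) & is.na(size)))
    stop("row ", row, ", column ", col, ": non-numeric lesion size",
         call. = FALSE)
  likert <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(likert))
    stop("row ", row, ", column ", col, ": non-integer likert score",
         call. = FALSE)
  data.frame(location = m[, 1], size_mm = size,
             multiple = m[, 3] == "1", likert = likert,
             stringsAsFactors = FALSE)
}

.parse_flag <- function(x, row, col) {
  if (!x %in% c("0", "1"))
    stop("row ", row, ", column ", col, ": expected 0 or 1, got '", x, "'",
         call. = FALSE)
  x == "1"
}

#' Read a screening cohort from disk
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @return A validated [as_cohort()] object.  Malformed rows raise an error
#'   naming the offending row and column; out-of-range values (likert outside
#'   0--5, non-positive sizes) raise validation errors.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "json") return(.read_cohort_json(path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    stop("csv header is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    likert_int <- function(col) {
      v <- suppressWarnings(as.integer(r[[col]]))
      if (is.na(v)) stop("row ", i, ", column ", col,
                         ": expected an integer", call. = FALSE)
      v
    }
    df <- data.frame(patient_id = r$patient_id,
                     primary_site = r$primary_site,
                     ct_call = r$ct_call,
                     ct_likert_max = likert_int("ct_likert_max"),
                     pet_call = r$pet_call,
                     pet_likert_max = likert_int("pet_likert_max"),
                     dm_at_screening = .parse_flag(r$dm_at_screening, i, "dm_at_screening"),
                     spt_at_screening = .parse_flag(r$spt_at_screening, i, "spt_at_screening"),
                     dm_within_12mo = .parse_flag(r$dm_within_12mo, i, "dm_within_12mo"),
                     spt_within_12mo = .parse_flag(r$spt_within_12mo, i, "spt_within_12mo"),
                     locoregional_control = .parse_flag(r$locoregional_control, i, "locoregional_control"),
                     confirmation = r$confirmation,
                     stringsAsFactors = FALSE)
    df$risk_factors <- list(strsplit(r$risk_factors, ";", fixed = TRUE)[[1]])
    df$ct_lesions <- list(.unpack_lesions(r$ct_lesions, i, "ct_lesions"))
    df$pet_lesions <- list(.unpack_lesions(r$pet_lesions, i, "pet_lesions"))
    df[, .cohort_columns]
  })
  if (length(records) == 0L) return(.empty_cohort())
  as_cohort(records)
}

.empty_cohort <- function() {
  df <- patient_record("x", "recurrence", "larynx",
                       modality_reading("negative"),
                       modality_reading("negative", modality = "pet"))[0, ]
  class(df) <- c("dm_cohort", "data.frame")
  df
}

#' Write a screening cohort to disk
#'
#' Round-trips with [read_cohort()]: `read_cohort(write_cohort(c))`
#' reproduces `c` field for field.
#'
#' @param cohort a `dm_cohort`.
#' @param path destination file.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  validate_cohort(cohort)
  if (format == "json") return(.write_cohort_json(cohort, path))
  flat <- data.frame(
    patient_id = cohort$patient_id,
    risk_factors = vapply(cohort$risk_factors, paste, "", collapse = ";"),
    primary_site = cohort$primary_site,
    ct_call = cohort$ct_call,
    ct_likert_max = cohort$ct_likert_max,
    ct_lesions = vapply(cohort$ct_lesions, .pack_lesions, ""),
    pet_call = cohort$pet_call,
    pet_likert_max = cohort$pet_likert_max,
    pet_lesions = vapply(cohort$pet_lesions, .pack_lesions, ""),
    dm_at_screening = as.integer(cohort$dm_at_screening),
    spt_at_screening = as.integer(cohort$spt_at_screening),
    dm_within_12mo = as.integer(cohort$dm_within_12mo),
    spt_within_12mo = as.integer(cohort$spt_within_12mo),
    locoregional_control = as.integer(cohort$locoregional_control),
    confirmation = cohort$confirmation,
    stringsAsFactors = FALSE)
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_cohort_json <- function(cohort, path) {
  patients <- lapply(seq_len(nrow(cohort)), function(i) {
    lesion_list <- function(df) {
      lapply(seq_len(nrow(df)), function(j)
        list(location = df$location[j],
             size_mm = if (is.na(df$size_mm[j])) NULL else df$size_mm[j],
             multiple = df$multiple[j],
             likert = df$likert[j]))
    }
    list(patient_id = cohort$patient_id[i],
         risk_factors = as.list(cohort$risk_factors[[i]]),
         primary_site = cohort$primary_site[i],
         ct = list(call = cohort$ct_call[i],
                   likert_max = cohort$ct_likert_max[i],
                   lesions = lesion_list(cohort$ct_lesions[[i]])),
         pet = list(call = cohort$pet_call[i],
                    likert_max = cohort$pet_likert_max[i],
                    lesions = lesion_list(cohort$pet_lesions[[i]])),
         outcome = list(dm_at_screening = cohort$dm_at_screening[i],
                        spt_at_screening = cohort$spt_at_screening[i],
                        dm_within_12mo = cohort$dm_within_12mo[i],
                        spt_within_12mo = cohort$spt_within_12mo[i],
                        locoregional_control = cohort$locoregional_control[i],
                        confirmation = cohort$confirmation[i]))
  })
  jsonlite::write_json(patients, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.read_cohort_json <- function(path) {
  patients <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(patients) == 0L) return(.empty_cohort())
  records <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    need <- c("patient_id", "risk_factors", "primary_site", "ct", "pet",
              "outcome")
    if (!all(need %in% names(p)))
      stop("json patient ", i, ": missing field(s) ",
           paste(setdiff(need, names(p)), collapse = ", "), call. = FALSE)
    lesion_df <- function(ls) {
      if (length(ls) == 0L) return(no_lesions())
      do.call(rbind, lapply(ls, function(l)
        data.frame(location = l$location,
                   size_mm = if (length(l$size_mm) != 1L) NA_real_
                             else as.numeric(l$size_mm),
                   multiple = isTRUE(l$multiple),
                   likert = as.integer(l$likert),
                   stringsAsFactors = FALSE)))
    }
    o <- p$outcome
    df <- data.frame(patient_id = p$patient_id,
                     primary_site = p$primary_site,
                     ct_call = p$ct$call,
                     ct_likert_max = as.integer(p$ct$likert_max),
                     pet_call = p$pet$call,
                     pet_likert_max = as.integer(p$pet$likert_max),
                     dm_at_screening = isTRUE(o$dm_at_screening),
                     spt_at_screening = isTRUE(o$spt_at_screening),
                     dm_within_12mo = isTRUE(o$dm_within_12mo),
                     spt_within_12mo = isTRUE(o$spt_within_12mo),
                     locoregional_control = isTRUE(o$locoregional_control),
                     confirmation = o$confirmation,
                     stringsAsFactors = FALSE)
    df$risk_factors <- list(unlist(p$risk_factors))
    df$ct_lesions <- list(lesion_df(p$ct$lesions))
    df$pet_lesions <- list(lesion_df(p$pet$lesions))
    df[, .cohort_columns]
  })
  as_cohort(records)
}
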