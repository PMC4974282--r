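# Diagnostic accuracy statistics: 2x2 tables, exact binomial confidence
# intervals, and the five standard screening metrics rendered as integer
# percentages.

#' Build a 2x2 contingency table from aligned calls and truths
#'
#' @param calls,truths equal-length `"positive"`/`"negative"` vectors, one
#'   element per patient.
#' @return A list of class `dm_table` with counts `tp`, `fp`, `fn`, `tn`.
#' @export
build_table <- function(calls, truths) {
  cls <- adjudicate(calls, truths)
  structure(list(tp = sum(cls == "TP"), fp = sum(cls == "FP"),
                 fn = sum(cls == "FN"), tn = sum(cls == "TN")),
            class = "dm_table")
}

#' @export
print.dm_table <- function(x, ...) {
  cat("<dm_table> TP=", x$tp, " FP=", x$fp, " FN=", x$fn, " TN=", x$tn,
      " (n=", x$tp + x$fp + x$fn + x$tn, ")\n", sep = "")
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail probabilities: the lower bound is the proportion
#' at which observing `k` or more successes has probability `(1-conf)/2`
#' (0 when `k = 0`), the upper bound the proportion at which observing `k` or
#' fewer has that probability (1 when `k = n`).  Computed through the
#' beta-quantile form of the tail inversion.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param conf confidence level, default 0.95.
#' @return `c(lower, upper)` on the proportion scale.
#' @examples
#' clopper_pearson(6, 12)   # 0.211 .. 0.789, printed as 21-79
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("clopper_pearson: k and n must be single numbers", call. = FALSE)
  if (n < 1 || k < 0 || k > n)
    stop("clopper_pearson: need 0 <= k <= n and n >= 1", call. = FALSE)
  alpha <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(alpha, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Proportion with exact confidence interval
#'
#' @inheritParams clopper_pearson
#' @return One-row data.frame: `numerator`, `denominator`, `point`,
#'   `ci_low`, `ci_high`, `conf`.  When `n = 0` the estimate is undefined and
#'   all value fields are `NA` (never an error: an all-negative cohort simply
#'   has no sensitivity).
#' @export
proportion_estimate <- function(k, n, conf = 0.95) {
  if (n == 0)
    return(data.frame(numerator = k, denominator = 0L, point = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_, conf = conf))
  ci <- clopper_pearson(k, n, conf)
  data.frame(numerator = as.integer(k), denominator = as.integer(n),
             point = k / n, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             conf = conf)
}

#' Sensitivity, specificity, PPV, NPV and accuracy for a 2x2 table
#'
#' @param table a [build_table()] result (or a list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @param conf confidence level for the exact intervals.
#' @return A data.frame of class `dm_accuracy_profile`, one row per metric
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`) with numerator,
#'   denominator, point estimate and exact interval.  Metrics whose
#'   denominator is zero are returned with `NA` values.
#' @export
accuracy_profile <- function(table, conf = 0.95) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("accuracy_profile: empty table", call. = FALSE)
  rows <- rbind(
    cbind(metric = "sensitivity", proportion_estimate(tp, tp + fn, conf)),
    cbind(metric = "specificity", proportion_estimate(tn, fp + tn, conf)),
    cbind(metric = "ppv",         proportion_estimate(tp, tp + fp, conf)),
    cbind(metric = "npv",         proportion_estimate(tn, fn + tn, conf)),
    cbind(metric = "accuracy",    proportion_estimate(tp + tn, total, conf)))
  class(rows) <- c("dm_accuracy_profile", "data.frame")
  rows
}

#' Round a proportion to an integer percentage, half away from zero
#'
#' The rendering convention of the reported tables: 37/40 = 92.5 prints as
#' 93, 35/40 = 87.5 as 88 (base `round()` would give 92 and 88 under
#' round-half-even).
#'
#' @param x proportion in `[0, 1]`.
#' @return Integer percentage.
#' @export
percent_half_up <- function(x) {
  ifelse(is.na(x), NA_integer_, as.integer(floor(x * 100 + 0.5)))
}

.render_cell <- function(row) {
  if (is.na(row$point)) return("—")
  sprintf("%d (%d–%d)", percent_half_up(row$point),
          percent_half_up(row$ci_low), percent_half_up(row$ci_high))
}

#' Render accuracy profiles as a percentage table
#'
#' One row per method, cells formatted `"P (L-H)"` as integer percentages
#' with the exact interval; undefined metrics render as an em-dash.
#'
#' @param profiles named list of [accuracy_profile()] results (names are the
#'   method labels, e.g. `CT`, `PET`, `PET and CT`).
#' @param n_label text describing the analysis set, printed in the header.
#' @return Character vector of report lines.
#' @export
render_table <- function(profiles, n_label = "") {
  stopifnot(length(profiles) >= 1L, !is.null(names(profiles)))
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  header <- sprintf("%-12s %-14s %-14s %-14s %-14s %-14s", "Method",
                    "Sensitivity", "Specificity", "PPV", "NPV", "Accuracy")
  lines <- c(sprintf("Percentage with %d %% confidence interval%s",
                     round(100 * profiles[[1]]$conf[1]),
                     if (nzchar(n_label)) paste0(" (", n_label, ")") else ""),
             header)
  for (nm in names(profiles)) {
    p <- profiles[[nm]]
    cells <- vapply(metrics, function(m) .render_cell(p[p$metric == m, ]), "")
    lines <- c(lines, sprintf("%-12s %-14s %-14s %-14s %-14s %-14s", nm,
                              cells[1], cells[2], cells[3], cells[4], cells[5]))
  }
  lines
}
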