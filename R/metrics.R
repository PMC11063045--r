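#' Per-class confusion counts
#'
#' Reduces a record table to the correct/total pair that defines one cell of
#' a screening performance table: for a disease class, `total` is the number
#' of records truly of that class and `correct` those counted as detected
#' under `positive_rule`; for the `"normal"` class, `correct` is the number
#' of true normals predicted normal (the specificity numerator).
#'
#' `positive_rule = "exact_class"` (the default) counts a disease record as
#' detected only when it is assigned its own class; `"any_disease"` counts
#' any non-normal prediction as a detection.
#'
#' @param records record tibble with predictions filled.
#' @param class_name the class to tabulate (a disease name or `"normal"`).
#' @param positive_rule `"exact_class"` or `"any_disease"`.
#' @return A `confusion_counts` object: list with `correct`, `total`,
#'   `class` and `rule`.
#' @export
class_confusion <- function(records, class_name,
                            positive_rule = c("exact_class", "any_disease")) {
  check_records(records)
  positive_rule <- match.arg(positive_rule)
  if (!nrow(records)) abort_sdca("record table is empty")
  in_class <- records$true_class == class_name
  if (!any(in_class))
    abort_sdca("class '", class_name, "' absent from the record table")
  pred <- records$predicted_class[in_class]
  correct <- if (class_name == NORMAL_CLASS) {
    sum(pred == NORMAL_CLASS)
  } else if (positive_rule == "exact_class") {
    sum(pred == class_name)
  } else {
    sum(pred != NORMAL_CLASS)
  }
  confusion_counts(correct, sum(in_class), class = class_name, rule = positive_rule)
}

#' Confusion counts entered directly
#'
#' Wraps a published correct-count / denominator pair (the
#' "percentage (count)" convention of screening performance tables) so the
#' metric functions can run without record-level data.
#'
#' @param correct non-negative integer, records counted correct.
#' @param total positive integer, class denominator.
#' @param class,rule optional labels carried along for display.
#' @export
confusion_counts <- function(correct, total, class = NA_character_,
                             rule = "exact_class") {
  if (length(correct) != 1L || length(total) != 1L ||
      !is.numeric(correct) || !is.numeric(total) ||
      is.na(correct) || is.na(total) ||
      correct != floor(correct) || total != floor(total))
    abort_sdca("`correct` and `total` must be single whole numbers")
  if (total < 1) abort_sdca("`total` must be positive")
  if (correct < 0 || correct > total)
    abort_sdca("need 0 <= correct <= total; got ", correct, "/", total)
  structure(list(correct = as.integer(correct), total = as.integer(total),
                 class = class, rule = rule),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> ", x$correct, "/", x$total,
      if (!is.na(x$class)) paste0(" (", x$class, ")"), "\n", sep = "")
  invisible(x)
}

#' Sensitivity and specificity as display percentages
#'
#' `100 * correct / total`, rounded half-up to two decimals — the display
#' convention of screening performance tables. The unrounded percentage is
#' kept in the `"unrounded"` attribute so downstream computation never
#' accumulates display rounding.
#'
#' @param counts a [confusion_counts()] (or [class_confusion()]) object.
#' @return Rounded percentage with attribute `unrounded`.
#' @examples
#' sensitivity_pct(confusion_counts(218, 287))  # 75.96
#' @export
sensitivity_pct <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  raw <- 100 * counts$correct / counts$total
  structure(round_half_up(raw, 2), unrounded = raw)
}

#' @rdname sensitivity_pct
#' @details `specificity_pct()` is the identical computation applied to the
#'   normal class (true negatives over all normals); it exists so call sites
#'   read as the quantity they report.
#' @export
specificity_pct <- function(counts) sensitivity_pct(counts)

#' Youden's index of a binary operating point
#'
#' J = sensitivity + specificity − 1, displayed half-up to four decimals.
#' By default (`rounding = "display"`) the two fractions are first taken to
#' the 2-decimal percentage scale, matching how published tables derive J
#' from their displayed percentages; `rounding = "none"` uses the raw
#' fractions.
#'
#' @param sens,spec fractions in `[0, 1]`.
#' @param rounding `"display"` or `"none"`.
#' @return J in `[-1, 1]`, rounded half-up to 4 decimals.
#' @examples
#' youden_index(483 / 502, 430 / 517)  # 0.7939
#' @export
youden_index <- function(sens, spec, rounding = c("display", "none")) {
  rounding <- match.arg(rounding)
  if (!is_fraction(sens) || !is_fraction(spec))
    abort_sdca("`sens` and `spec` must be fractions in [0, 1]")
  if (rounding == "display") {
    sens <- round_half_up(100 * sens, 2) / 100
    spec <- round_half_up(100 * spec, 2) / 100
  }
  round_half_up(sens + spec - 1, 4)
}

#' Area under the ROC curve by the trapezoidal rule
#'
#' Computed through the rank (Mann-Whitney) formulation, which is exactly
#' the trapezoidal area of the empirical ROC with tied scores averaged.
#'
#' @param scores numeric scores, higher meaning more disease-like.
#' @param labels binary labels (0/1 or logical), at least one of each.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels) || !length(scores))
    abort_sdca("`scores` and `labels` must be non-empty and the same length")
  if (anyNA(scores) || anyNA(labels) || !all(labels %in% c(0L, 1L)))
    abort_sdca("labels must be binary 0/1 without missing values")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    abort_sdca("need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Performance table for one or many models
#'
#' Computes the per-class counts, display percentage and per-model Youden's
#' index (first disease-class sensitivity paired with the normal-class
#' specificity when a single disease is tabulated, otherwise one J per
#' disease) from a record table containing one or more `model_name` values.
#'
#' @inheritParams class_confusion
#' @param classes classes to tabulate; default: every class present, normal
#'   last.
#' @return Tibble with one row per (model, class): `model`, `class`,
#'   `metric` (sensitivity/specificity), `correct`, `total`, `pct` (2-dp
#'   display), `pct_raw`, and `youden` (disease rows only; `NA` when the
#'   table has no normal class to pair with).
#' @export
screening_metrics <- function(records, classes = NULL,
                              positive_rule = c("exact_class", "any_disease")) {
  check_records(records)
  positive_rule <- match.arg(positive_rule)
  if (is.null(classes)) {
    classes <- sort(unique(records$true_class))
    classes <- c(setdiff(classes, NORMAL_CLASS), intersect(NORMAL_CLASS, classes))
  }
  models <- unique(records$model_name)
  rows <- list()
  for (m in models) {
    sub <- records[records$model_name == m, , drop = FALSE]
    spec_frac <- NA_real_
    if (NORMAL_CLASS %in% classes && any(sub$true_class == NORMAL_CLASS)) {
      cc <- class_confusion(sub, NORMAL_CLASS, positive_rule)
      spec_frac <- cc$correct / cc$total
    }
    for (cl in classes) {
      cc <- class_confusion(sub, cl, positive_rule)
      pct <- sensitivity_pct(cc)
      praw <- attr(pct, "unrounded")
      is_disease <- cl != NORMAL_CLASS
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = m, class = cl,
        metric = if (is_disease) "sensitivity" else "specificity",
        correct = cc$correct, total = cc$total,
        pct = as.numeric(pct), pct_raw = praw,
        youden = if (is_disease && !is.na(spec_frac))
          youden_index(cc$correct / cc$total, spec_frac) else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}
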