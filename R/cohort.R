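#' Define a screening cohort
#'
#' A cohort specification fixes the disease vocabulary, the per-disease
#' prevalences and the number of subjects for a hypothetical screening
#' population. Diseases are mutually exclusive per subject; whatever
#' probability mass the prevalences leave over is the normal (disease-free)
#' class, so the prevalences must sum to strictly less than 1.
#'
#' @param diseases character vector of disease names (must not contain
#'   `"normal"`, which is reserved for the disease-free remainder).
#' @param prevalence named numeric vector of per-disease prevalences in
#'   `[0, 1)`; names must match `diseases`.
#' @param size positive integer, number of subjects in the cohort.
#' @param setting_label free-text label for the setting the prevalences
#'   describe (e.g. `"urban"` or `"rural"`).
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec(c("AMD", "DR", "PM"),
#'             c(AMD = 0.026, DR = 0.018, PM = 0.010),
#'             size = 100000, setting_label = "urban")
#' @export
cohort_spec <- function(diseases, prevalence, size, setting_label = "") {
  if (!is.character(diseases) || length(diseases) < 1L || anyDuplicated(diseases))
    abort_sdca("`diseases` must be a non-empty character vector without duplicates")
  if (NORMAL_CLASS %in% diseases)
    abort_sdca("'", NORMAL_CLASS, "' is reserved for the disease-free class")
  if (is.null(names(prevalence)) || !setequal(names(prevalence), diseases))
    abort_sdca("`prevalence` must be named and cover exactly the declared diseases")
  prevalence <- prevalence[diseases]
  if (!is.numeric(prevalence) || any(!is.finite(prevalence)) ||
      any(prevalence < 0) || any(prevalence >= 1))
    abort_sdca("prevalences must be finite fractions in [0, 1)")
  if (sum(prevalence) >= 1)
    abort_sdca("prevalences must sum to < 1 (remainder is the normal class); got ",
               paste(sprintf("%s=%g", names(prevalence), prevalence), collapse = ", "),
               " summing to ", format(sum(prevalence)))
  if (length(size) != 1L || !is.numeric(size) || is.na(size) ||
      size < 1 || size != floor(size))
    abort_sdca("`size` must be a positive whole number")
  structure(
    list(diseases = diseases, prevalence = prevalence,
         size = as.integer(size), setting_label = as.character(setting_label)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$size, " subjects",
      if (nzchar(x$setting_label)) paste0(" (", x$setting_label, ")"), "\n", sep = "")
  cat("  prevalence: ",
      paste(sprintf("%s %.4g", names(x$prevalence), x$prevalence), collapse = ", "),
      "; normal ", format(1 - sum(x$prevalence)), "\n", sep = "")
  invisible(x)
}

#' Define a screening classifier's operating point
#'
#' Parameterises the forward model the simulator applies to true classes:
#' a subject with disease `d` is flagged as `d` with probability
#' `sensitivity[d]`, and a normal subject is flagged normal with probability
#' `specificity`. What happens on an error is policy: a missed disease case
#' goes where `miss_target` says (default `"normal"`, i.e. cross-disease
#' confusions are not modelled), and a false-positive normal is assigned a
#' disease according to `false_positive_target` (default `"uniform"` over the
#' declared diseases, or the name of a single disease).
#'
#' @param sensitivity named numeric vector of per-disease sensitivities in
#'   `[0, 1]`.
#' @param specificity numeric scalar in `[0, 1]`, probability that a normal
#'   subject is classified normal.
#' @param miss_target `"normal"` or `"uniform_other"` (spread a missed case
#'   uniformly over the other diseases, or to normal if there is none).
#' @param false_positive_target `"uniform"` or the name of one disease in
#'   `names(sensitivity)`.
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec(c(AMD = 0.7596, DR = 0.9525, PM = 1), specificity = 0.9247)
#' @export
classifier_spec <- function(sensitivity, specificity,
                            miss_target = c("normal", "uniform_other"),
                            false_positive_target = "uniform") {
  if (is.null(names(sensitivity)) || any(!nzchar(names(sensitivity))))
    abort_sdca("`sensitivity` must be a named vector (one entry per disease)")
  if (!is_fraction(sensitivity))
    abort_sdca("sensitivities must be fractions in [0, 1]")
  if (length(specificity) != 1L || !is_fraction(specificity))
    abort_sdca("`specificity` must be a single fraction in [0, 1]")
  miss_target <- match.arg(miss_target)
  if (length(false_positive_target) != 1L ||
      !(false_positive_target %in% c("uniform", names(sensitivity))))
    abort_sdca("`false_positive_target` must be \"uniform\" or one of: ",
               paste(names(sensitivity), collapse = ", "))
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         miss_target = miss_target, false_positive_target = false_positive_target),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("<classifier_spec> specificity ", format(x$specificity), "; sensitivity ",
      paste(sprintf("%s %.4g", names(x$sensitivity), x$sensitivity), collapse = ", "),
      "\n  miss -> ", x$miss_target, ", false positive -> ", x$false_positive_target,
      "\n", sep = "")
  invisible(x)
}

#' Draw the true disease classes of a cohort
#'
#' Samples each subject's true class independently with the cohort's
#' prevalences (remaining probability to `"normal"`). The RNG state is
#' threaded through the explicit `seed` and the caller's global RNG state is
#' left untouched; the same `(spec, seed)` always yields the identical table.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A tibble of screening records (`record_id`, `true_class`,
#'   `predicted_class`, `model_name`) with `predicted_class` and
#'   `model_name` set to `NA` until [apply_classifier()] fills them.
#' @seealso [apply_classifier()], [simulate_cohort()]
#' @export
draw_true_classes <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_seed(seed)
  classes <- c(spec$diseases, NORMAL_CLASS)
  probs <- c(spec$prevalence, 1 - sum(spec$prevalence))
  truth <- withr::with_seed(seed,
    sample(classes, spec$size, replace = TRUE, prob = probs))
  tibble::tibble(
    record_id = sprintf("S%07d", seq_len(spec$size)),
    true_class = truth,
    predicted_class = NA_character_,
    model_name = NA_character_
  )
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) || seed != floor(seed))
    abort_sdca("`seed` must be a single whole number")
  invisible(as.integer(seed))
}

#' Apply a classifier's operating point to true classes
#'
#' Fills `predicted_class` by the forward model of [classifier_spec()]:
#' correct detection with the per-disease sensitivity, correct rejection of
#' normals with the specificity, and the configured policies on errors.
#'
#' @param records record tibble with `true_class` filled (all classes must be
#'   covered by `names(clf$sensitivity)` plus `"normal"`).
#' @param clf a [classifier_spec()].
#' @param seed integer seed.
#' @param model_name label written into the `model_name` column.
#' @return The record tibble with `predicted_class` and `model_name` filled.
#' @export
apply_classifier <- function(records, clf, seed, model_name = "model") {
  check_records(records, require_predictions = FALSE)
  stopifnot(inherits(clf, "classifier_spec"))
  check_seed(seed)
  diseases <- names(clf$sensitivity)
  known <- c(diseases, NORMAL_CLASS)
  bad <- setdiff(unique(records$true_class), known)
  if (length(bad))
    abort_sdca("record table contains true classes unknown to the classifier: ",
               paste(bad, collapse = ", "))

  n <- nrow(records)
  truth <- records$true_class
  pred <- withr::with_seed(seed, {
    u <- stats::runif(n)
    out <- character(n)
    is_norm <- truth == NORMAL_CLASS
    # normals: specificity, else a disease per the false-positive policy
    hit <- is_norm & u < clf$specificity
    out[hit] <- NORMAL_CLASS
    fp <- is_norm & !hit
    if (any(fp)) {
      out[fp] <- if (clf$false_positive_target == "uniform")
        sample(diseases, sum(fp), replace = TRUE)
      else clf$false_positive_target
    }
    # disease cases: per-disease sensitivity, else the miss policy
    for (d in diseases) {
      idx <- which(truth == d)
      if (!length(idx)) next
      det <- u[idx] < clf$sensitivity[[d]]
      out[idx[det]] <- d
      miss <- idx[!det]
      if (length(miss)) {
        out[miss] <- if (clf$miss_target == "normal" || length(diseases) == 1L)
          NORMAL_CLASS
        else sample(setdiff(diseases, d), length(miss), replace = TRUE)
      }
    }
    out
  })
  records$predicted_class <- pred
  records$model_name <- model_name
  records
}

#' Simulate a screened cohort in one call
#'
#' Convenience wrapper: [draw_true_classes()] then [apply_classifier()].
#' Distinct sub-seeds are derived from `seed` so that two models applied to
#' the same cohort share the truth draw but not the classification noise.
#'
#' @inheritParams draw_true_classes
#' @inheritParams apply_classifier
#' @export
simulate_cohort <- function(spec, clf, seed, model_name = "model") {
  truth <- draw_true_classes(spec, seed)
  apply_classifier(truth, clf, seed = (seed * 7919L) %% .Machine$integer.max,
                   model_name = model_name)
}

check_records <- function(records, require_predictions = TRUE) {
  if (!is.data.frame(records))
    abort_sdca("`records` must be a data frame of screening records")
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols))
    abort_sdca("record table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$record_id))
    abort_sdca("record_id values must be unique within a table")
  if (anyNA(records$true_class))
    abort_sdca("true_class must be filled for every record")
  if (require_predictions && anyNA(records$predicted_class))
    abort_sdca("predicted_class must be filled for every record")
  invisible(records)
}
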