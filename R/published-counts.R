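#' Published operating counts from a community fundus-screening test set
#'
#' Example data: the per-class correct counts of three deployed screening
#' models — a foundation-model-based classifier ("RETFound") and two
#' commercial systems ("Model S", "Model Y") — on a community screening test
#' set of 1890 fundus images (287 age-related macular degeneration, 337
#' diabetic retinopathy, 151 pathologic myopia, 1115 normal fundus).
#' Disease rows carry sensitivity numerators; the `normal` row carries the
#' specificity numerator. These counts drive every model-comparison example
#' in the package without any record-level data.
#'
#' @return Tibble with columns `model`, `class`, `correct`, `total`.
#' @examples
#' counts <- fundus_screening_counts()
#' amd <- subset(counts, class == "AMD")
#' compare_models(contingency_counts(amd$model, amd$correct, amd$total))
#' @export
fundus_screening_counts <- function() {
  tibble::tibble(
    model = rep(c("RETFound", "Model S", "Model Y"), each = 4L),
    class = rep(c("AMD", "DR", "PM", "normal"), times = 3L),
    correct = c(218L, 321L, 151L, 1031L,
                176L, 266L,  90L,  866L,
                170L, 240L, 109L,  821L),
    total = rep(c(287L, 337L, 151L, 1115L), times = 3L)
  )
}

#' Published diabetic-retinopathy validation counts for three architectures
#'
#' Example data: internal- and external-validation operating counts of three
#' deep-learning architectures (a retinal foundation model and two ImageNet
#' CNNs) on a binary diabetic-retinopathy task. Internal validation: 502 DR
#' and 517 normal images; external validation: 337 DR and 1115 normal.
#' Used by the Youden's-index examples.
#'
#' @return Tibble with columns `model`, `validation`
#'   (`"internal"`/`"external"`), `sens_correct`, `sens_total`,
#'   `spec_correct`, `spec_total`.
#' @examples
#' dr <- dr_validation_counts()
#' with(dr[1, ], youden_index(sens_correct / sens_total,
#'                            spec_correct / spec_total))
#' @export
dr_validation_counts <- function() {
  tibble::tibble(
    model = rep(c("RETFound", "EfficientNetB3", "ResNet50"), times = 2L),
    validation = rep(c("internal", "external"), each = 3L),
    sens_correct = c(483L, 455L, 466L, 279L, 229L, 208L),
    sens_total = rep(c(502L, 337L), each = 3L),
    spec_correct = c(430L, 453L, 444L, 875L, 921L, 1021L),
    spec_total = rep(c(517L, 1115L), each = 3L)
  )
}

#' Per-metric contingency tables from a counts table
#'
#' Splits a `model, class, correct, total` counts table (such as
#' [fundus_screening_counts()]) into one [contingency_counts()] table per
#' class, ready for [compare_models()].
#'
#' @param counts tibble with columns `model`, `class`, `correct`, `total`.
#' @return Named list of `contingency_counts`, one per class.
#' @export
counts_by_class <- function(counts) {
  stopifnot(all(c("model", "class", "correct", "total") %in% names(counts)))
  out <- lapply(split(counts, counts$class), function(sub) {
    if (length(unique(sub$total)) != 1L)
      abort_sdca("models disagree on the denominator for class '",
                 sub$class[1L], "'")
    contingency_counts(sub$model, sub$correct, sub$total)
  })
  out[unique(counts$class)]
}
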