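#' Net benefit of a screening test, closed form
#'
#' The net benefit of referring screen-positives at probability threshold
#' `p_t` is
#' \deqn{NB = TP/n - \frac{p_t}{1-p_t} \times FP/n,}
#' the per-person rate of true positives minus false positives down-weighted
#' by the odds of the threshold: `p_t` is the disease risk at which a
#' clinician is indifferent between referring and not referring, so one
#' false referral costs `p_t/(1-p_t)` of a true one.
#'
#' For a test with the given operating point applied to a population with
#' the given prevalence, the expected counts are `TP = n * prevalence *
#' sens` and `FP = n * (1 - prevalence) * (1 - spec)`; they are kept
#' fractional (expected persons, not rounded to whole subjects).
#'
#' @param sens,spec operating point of the test, fractions in `[0, 1]`.
#' @param prevalence disease prevalence in `[0, 1]`.
#' @param p_t probability threshold(s), each strictly inside `(0, 1)` — the
#'   odds weight is undefined at 1.
#' @param n cohort size (default the conventional hypothetical cohort of
#'   100,000; the net benefit itself is per-person and independent of `n`).
#' @return Tibble with one row per threshold: `threshold`, `tp`, `fp`, `n`,
#'   `net_benefit`.
#' @examples
#' nb_test_closed(sens = 0.7596, spec = 0.9247, prevalence = 0.05, p_t = 0.1)
#' @export
nb_test_closed <- function(sens, spec, prevalence, p_t, n = 100000) {
  for (v in list(sens = sens, spec = spec, prevalence = prevalence))
    if (length(v) != 1L || !is_fraction(v))
      abort_sdca("`sens`, `spec` and `prevalence` must be single fractions in [0, 1]")
  check_thresholds(p_t)
  if (length(n) != 1L || !is.numeric(n) || n <= 0) abort_sdca("`n` must be positive")
  tp <- n * prevalence * sens
  fp <- n * (1 - prevalence) * (1 - spec)
  tibble::tibble(threshold = p_t, tp = tp, fp = fp, n = n,
                 net_benefit = tp / n - p_t / (1 - p_t) * fp / n)
}

check_thresholds <- function(p_t) {
  if (!length(p_t) || !is.numeric(p_t) || any(!is.finite(p_t)) ||
      any(p_t <= 0) || any(p_t >= 1))
    abort_sdca("thresholds must lie strictly inside (0, 1)")
  invisible(p_t)
}

#' Net benefit of the treat-all reference strategy
#'
#' Referring everyone yields `TP = n * prevalence`, `FP = n *
#' (1 - prevalence)`, hence `NB = prevalence - (1 - prevalence) *
#' p_t / (1 - p_t)`: positive below the prevalence, zero exactly at
#' `p_t = prevalence`, negative above.
#'
#' @inheritParams nb_test_closed
#' @export
nb_treat_all <- function(prevalence, p_t, n = 100000) {
  nb_test_closed(sens = 1, spec = 0, prevalence = prevalence, p_t = p_t, n = n)
}

#' Net benefit of the treat-none reference strategy
#'
#' Referring no one: zero true and false positives, net benefit identically
#' zero at every threshold.
#'
#' @inheritParams nb_test_closed
#' @export
nb_treat_none <- function(p_t, n = 100000) {
  check_thresholds(p_t)
  tibble::tibble(threshold = p_t, tp = 0, fp = 0, n = n, net_benefit = 0)
}

#' Net benefit measured on a record table
#'
#' The empirical counterpart of [nb_test_closed()]: counts actual true and
#' false positives in a (typically simulated) screened cohort. A record is
#' screen-positive under `positive_rule = "any_disease"` when its prediction
#' is any disease, and under `"exact_class"` when its prediction equals
#' `disease`. True positives are screen-positives whose truth matches the
#' same definition; false positives are screen-positives that are truly
#' normal.
#'
#' @param records record tibble with predictions filled.
#' @inheritParams nb_test_closed
#' @param positive_rule `"any_disease"` or `"exact_class"`.
#' @param disease target disease, required for `"exact_class"`.
#' @export
nb_empirical <- function(records, p_t,
                         positive_rule = c("any_disease", "exact_class"),
                         disease = NULL) {
  check_records(records)
  if (!nrow(records)) abort_sdca("record table is empty")
  positive_rule <- match.arg(positive_rule)
  check_thresholds(p_t)
  if (positive_rule == "any_disease") {
    pos <- records$predicted_class != NORMAL_CLASS
    truly <- records$true_class != NORMAL_CLASS
  } else {
    if (is.null(disease)) abort_sdca("`disease` is required for exact_class")
    pos <- records$predicted_class == disease
    truly <- records$true_class == disease
  }
  n <- nrow(records)
  tp <- sum(pos & truly)
  fp <- sum(pos & records$true_class == NORMAL_CLASS)
  tibble::tibble(threshold = p_t, tp = tp, fp = fp, n = n,
                 net_benefit = tp / n - p_t / (1 - p_t) * fp / n)
}

#' Effective operating point for combined multi-disease screening
#'
#' Reduces per-disease operating points to a single "any targeted disease"
#' screen under mutual exclusivity: the combined prevalence is the sum of
#' the per-disease prevalences, the combined sensitivity their
#' prevalence-weighted mean, and the combined specificity the normal-class
#' specificity unchanged (a normal subject is a combined false positive
#' exactly when flagged with any disease). The rule is isolated here so an
#' alternative combination can be swapped in.
#'
#' @param sens named per-disease sensitivities, fractions.
#' @param prevalence named per-disease prevalences (same names as `sens`),
#'   summing to < 1.
#' @param spec normal-class specificity, fraction.
#' @return List with `sens`, `spec`, `prevalence` for [nb_test_closed()].
#' @export
combined_screening <- function(sens, prevalence, spec) {
  if (!length(sens)) abort_sdca("empty disease list")
  if (is.null(names(sens)) || is.null(names(prevalence)) ||
      !setequal(names(sens), names(prevalence)))
    abort_sdca("`sens` and `prevalence` must share the same disease names")
  prevalence <- prevalence[names(sens)]
  if (!is_fraction(sens) || !is_fraction(prevalence) || !is_fraction(spec))
    abort_sdca("all inputs must be fractions in [0, 1]")
  p <- sum(prevalence)
  if (p >= 1) abort_sdca("prevalences must sum to < 1")
  if (p == 0) abort_sdca("combined screening needs positive total prevalence")
  list(sens = sum(prevalence * sens) / p, spec = unname(spec), prevalence = p)
}

#' Decision curves for a set of screening models
#'
#' Builds the closed-form net benefit curve of every model plus the
#' treat-all and treat-none references over a common threshold grid. The
#' per-model operating point is either a single-disease `(sens, spec)` pair
#' evaluated at `prevalence`, or, when `prevalence` is a named vector, the
#' combined multi-disease screen of [combined_screening()].
#'
#' @param models named list; each element a list with `sens` and `spec`
#'   (scalar for single-disease, named vector `sens` for combined).
#' @param prevalence scalar prevalence or named per-disease vector.
#' @param thresholds grid of probability thresholds in `(0, 1)`, strictly
#'   increasing; default 0.01 to 0.99 in 1% steps.
#' @param n cohort size.
#' @param setting_label carried into the output.
#' @return Tibble: `setting`, `strategy`, `threshold`, `tp`, `fp`, `n`,
#'   `net_benefit`; one `strategy` per model plus `"treat_all"` and
#'   `"treat_none"`.
#' @export
build_curves <- function(models, prevalence,
                         thresholds = seq(0.01, 0.99, by = 0.01),
                         n = 100000, setting_label = "") {
  check_thresholds(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE))
    abort_sdca("`thresholds` must be strictly increasing")
  if (!length(models) || is.null(names(models)) || anyDuplicated(names(models)))
    abort_sdca("`models` must be a uniquely named list of operating points")
  combined <- length(prevalence) > 1L || !is.null(names(prevalence))
  curves <- lapply(names(models), function(nm) {
    op <- models[[nm]]
    pt <- if (combined) combined_screening(op$sens, prevalence, op$spec)
          else list(sens = op$sens, spec = op$spec, prevalence = prevalence)
    cbind(strategy = nm,
          nb_test_closed(pt$sens, pt$spec, pt$prevalence, thresholds, n))
  })
  p_all <- if (combined) sum(prevalence) else prevalence
  curves <- c(curves,
              list(cbind(strategy = "treat_all",
                         nb_treat_all(p_all, thresholds, n)),
                   cbind(strategy = "treat_none",
                         nb_treat_none(thresholds, n))))
  out <- do.call(rbind, curves)
  tibble::as_tibble(cbind(setting = setting_label, out))
}

#' Thresholds on which one strategy dominates all others
#'
#' Scans a shared threshold grid and reports, per strategy, the maximal
#' contiguous intervals on which its net benefit strictly exceeds every
#' other strategy's. Grid points where two or more strategies tie for the
#' maximum belong to no interval (no single maximiser).
#'
#' @param curves output of [build_curves()] (>= 2 strategies on one grid).
#' @return Tibble `strategy`, `lower`, `upper` (interval endpoints are grid
#'   thresholds; single-point runs have `lower == upper`).
#' @export
dominance_intervals <- function(curves) {
  stopifnot(is.data.frame(curves),
            all(c("strategy", "threshold", "net_benefit") %in% names(curves)))
  strategies <- unique(curves$strategy)
  if (length(strategies) < 2L) abort_sdca("need >= 2 strategies")
  grid <- sort(unique(curves$threshold))
  nb <- sapply(strategies, function(s) {
    sub <- curves[curves$strategy == s, ]
    if (!identical(sort(sub$threshold), grid))
      abort_sdca("strategies are not on a shared threshold grid")
    sub$net_benefit[order(sub$threshold)]
  })
  top <- apply(nb, 1L, function(row) {
    i <- which(row == max(row))
    if (length(i) == 1L) strategies[i] else NA_character_
  })
  rows <- list()
  for (s in strategies) {
    runs <- rle(!is.na(top) & top == s)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strategy = s, lower = grid[starts[j]], upper = grid[ends[j]])
    }
  }
  if (!length(rows))
    return(tibble::tibble(strategy = character(), lower = numeric(),
                          upper = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$lower, out$strategy), ]
}

#' Plot decision curves
#'
#' Convenience ggplot of [build_curves()] output: net benefit against the
#' probability threshold, one line per strategy. The values, not the plot,
#' are the contract; requires ggplot2.
#'
#' @param curves output of [build_curves()].
#' @param ymin lower clip for the y axis (treat-all dives steeply; clipping
#'   keeps the region of interest readable).
#' @export
plot_decision_curves <- function(curves, ymin = -0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort_sdca("plot_decision_curves() needs the ggplot2 package")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(ymin, NA)) +
    ggplot2::labs(x = "probability threshold", y = "net benefit") +
    ggplot2::theme_minimal()
}
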