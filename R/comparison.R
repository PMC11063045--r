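#' Correct/incorrect contingency table across screening models
#'
#' An r x 2 table with one row per model: the number of records of some
#' class it classified correctly and the number it got wrong. All models
#' must be measured on the same denominator (the same set of images), which
#' is the structure the omnibus and pairwise comparisons assume.
#'
#' @param models character vector of model names (>= 2, unique).
#' @param correct integer vector of correct counts, one per model.
#' @param total integer vector (or scalar) of class denominators per model.
#' @return A `contingency_counts` object (tibble with columns `model`,
#'   `correct`, `incorrect`).
#' @examples
#' contingency_counts(c("A", "B", "C"), correct = c(218, 176, 170), total = 287)
#' @export
contingency_counts <- function(models, correct, total) {
  if (length(models) < 2L || anyDuplicated(models))
    abort_sdca("need at least 2 uniquely named models")
  total <- rep_len(total, length(models))
  if (length(correct) != length(models))
    abort_sdca("`correct` must have one entry per model")
  if (any(correct < 0) || any(total <= 0) || any(correct > total))
    abort_sdca("need 0 <= correct <= total with positive totals")
  out <- tibble::tibble(model = as.character(models),
                        correct = as.integer(correct),
                        incorrect = as.integer(total - correct))
  class(out) <- c("contingency_counts", class(out))
  out
}

as_matrix_rx2 <- function(tab) {
  m <- cbind(correct = tab$correct, incorrect = tab$incorrect)
  rownames(m) <- tab$model
  m
}

comparison_result <- function(method, statistic, df, p_value,
                              alpha_prime = NA_real_, groups = NULL) {
  structure(
    list(method = method,
         statistic = if (is.null(statistic)) NA_real_ else unname(statistic),
         df = if (is.null(df)) NA_integer_ else as.integer(df),
         p_value = unname(p_value),
         alpha_prime = alpha_prime,
         significant = unname(p_value) < (if (is.na(alpha_prime)) 0.05 else alpha_prime),
         groups = groups),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$method,
      if (!is.null(x$groups)) paste0(" [", paste(x$groups, collapse = " vs "), "]"),
      "\n", sep = "")
  if (!is.na(x$statistic))
    cat("  statistic = ", format(round_half_up(x$statistic, 2), nsmall = 2),
        ", df = ", x$df, "\n", sep = "")
  cat("  p = ", format.pval(x$p_value, digits = 3),
      if (!is.na(x$alpha_prime)) paste0(" (alpha' = ", format(x$alpha_prime), ")"),
      if (x$significant) "  *significant*", "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test on an r x 2 table
#'
#' The uncorrected Pearson statistic (no Yates continuity correction at any
#' table size): published pairwise comparisons of screening sensitivities
#' match the uncorrected statistic, and the correction would break that
#' correspondence. Upper-tail p from the chi-square distribution with
#' `r - 1` degrees of freedom.
#'
#' @param tab a [contingency_counts()] table.
#' @return A `comparison_result` (method `"pearson_chi2"`).
#' @export
pearson_chi2 <- function(tab) {
  stopifnot(inherits(tab, "contingency_counts"))
  m <- as_matrix_rx2(tab)
  if (any(colSums(m) == 0))
    abort_sdca("a column margin is zero (all models all-correct or all-wrong); ",
               "the chi-square statistic is undefined - use Fisher's exact test")
  ct <- stats::chisq.test(m, correct = FALSE)
  comparison_result("pearson_chi2", ct$statistic, ct$parameter, ct$p.value,
                    groups = tab$model)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p by the point-probability rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the probability of the observed table.
#'
#' @param tab a [contingency_counts()] table with exactly 2 groups.
#' @return A `comparison_result` (method `"fisher_exact"`, no statistic).
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(inherits(tab, "contingency_counts"))
  if (nrow(tab) != 2L) abort_sdca("fisher_exact_2x2 needs exactly 2 groups")
  ft <- stats::fisher.test(as_matrix_rx2(tab))
  comparison_result("fisher_exact", NULL, NULL, ft$p.value, groups = tab$model)
}

# number of r x 2 tables with the given row totals and first-column total;
# simple DP over models, used only to police the enumeration guard
count_admissible_tables <- function(row_totals, col1_total) {
  counts <- rep(0, col1_total + 1L)   # counts[k+1]: ways to put k in column 1 so far
  counts[1L] <- 1
  for (rt in row_totals) {
    nxt <- rep(0, col1_total + 1L)
    for (k in 0:col1_total) {
      if (counts[k + 1L] == 0) next
      hi <- min(rt, col1_total - k)
      nxt[(k:(k + hi)) + 1L] <- nxt[(k:(k + hi)) + 1L] + counts[k + 1L]
    }
    counts <- nxt
  }
  counts[col1_total + 1L]
}

#' Freeman-Halton exact test on an r x 2 table
#'
#' Extension of Fisher's exact test beyond 2 x 2: the p-value is the sum of
#' multivariate hypergeometric probabilities of every table with the
#' observed margins that is no more probable than the observed one. Exact
#' enumeration is attempted only while the number of admissible tables is at
#' most `guard`; larger problems fall back to a seeded Monte-Carlo p-value
#' when `monte_carlo = TRUE` and are an error otherwise.
#'
#' @param tab a [contingency_counts()] table with >= 3 groups.
#' @param guard maximum number of admissible tables for exact enumeration.
#' @param monte_carlo allow the Monte-Carlo fallback past the guard.
#' @param mc_reps Monte-Carlo replicates.
#' @param seed seed for the Monte-Carlo route.
#' @return A `comparison_result` (method `"fisher_exact"`).
#' @export
fisher_freeman_halton <- function(tab, guard = 10000, monte_carlo = FALSE,
                                  mc_reps = 1e5, seed = 1L) {
  stopifnot(inherits(tab, "contingency_counts"))
  if (nrow(tab) < 3L)
    abort_sdca("Freeman-Halton needs >= 3 groups; use fisher_exact_2x2")
  m <- as_matrix_rx2(tab)
  n_tables <- count_admissible_tables(rowSums(m), sum(m[, 1L]))
  if (n_tables <= guard) {
    ft <- stats::fisher.test(m, workspace = 2e7)
    return(comparison_result("fisher_exact", NULL, NULL, ft$p.value,
                             groups = tab$model))
  }
  if (!monte_carlo)
    abort_sdca("table admits ", n_tables, " > ", guard, " configurations; ",
               "enable `monte_carlo = TRUE` for a simulated p-value")
  ft <- withr::with_seed(check_seed(seed),
    stats::fisher.test(m, simulate.p.value = TRUE, B = as.integer(mc_reps)))
  comparison_result("fisher_exact_mc", NULL, NULL, ft$p.value, groups = tab$model)
}

#' Choose between chi-square and exact testing
#'
#' The selection rule: Fisher's exact route whenever any expected cell count
#' (from the row/column margins) falls below 5 or any observed cell is 0;
#' the Pearson chi-square otherwise. The rule mirrors standard contingency
#' table practice and can be overridden by calling a test directly.
#'
#' @param tab a [contingency_counts()] table.
#' @return `"fisher_exact"` or `"pearson_chi2"`.
#' @export
choose_method <- function(tab) {
  stopifnot(inherits(tab, "contingency_counts"))
  m <- as_matrix_rx2(tab)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5) || any(m == 0)) "fisher_exact" else "pearson_chi2"
}

run_chosen_test <- function(tab, method = choose_method(tab), ...) {
  if (method == "pearson_chi2") return(pearson_chi2(tab))
  if (nrow(tab) == 2L) fisher_exact_2x2(tab) else fisher_freeman_halton(tab, ...)
}

#' Omnibus and Bonferroni-corrected pairwise model comparison
#'
#' The full post-hoc procedure for one performance metric: an omnibus test
#' across all models on the r x 2 correct/incorrect table (method chosen by
#' [choose_method()]), followed — only when the omnibus p-value falls below
#' `alpha` — by all pairwise 2 x 2 tests, each judged against the Bonferroni
#' level alpha' = `alpha / k_pairwise`.
#'
#' @param tab a [contingency_counts()] table (>= 2 models, common
#'   denominator definition).
#' @param alpha family-wise significance level for the omnibus test.
#' @param k_pairwise number of pairwise comparisons the Bonferroni
#'   correction divides by; defaults to the number of model pairs.
#' @param ... passed to [fisher_freeman_halton()] when the exact omnibus
#'   route is taken.
#' @return List with `omnibus` (a `comparison_result`) and `pairwise` (a
#'   tibble, empty when the omnibus is not significant): columns `model_a`,
#'   `model_b`, `method`, `statistic`, `df`, `p_value`, `alpha_prime`,
#'   `significant`.
#' @examples
#' dr <- contingency_counts(c("RET", "S", "Y"), c(321, 266, 240), 337)
#' compare_models(dr)
#' @export
compare_models <- function(tab, alpha = 0.05,
                           k_pairwise = choose(nrow(tab), 2), ...) {
  stopifnot(inherits(tab, "contingency_counts"))
  if (length(alpha) != 1L || !is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort_sdca("`alpha` must be in (0, 1)")
  omnibus <- run_chosen_test(tab, ...)
  omnibus$alpha_prime <- alpha
  omnibus$significant <- omnibus$p_value < alpha

  empty <- tibble::tibble(model_a = character(), model_b = character(),
                          method = character(), statistic = numeric(),
                          df = integer(), p_value = numeric(),
                          alpha_prime = numeric(), significant = logical())
  if (!omnibus$significant || nrow(tab) == 2L)
    return(list(omnibus = omnibus, pairwise = empty))

  alpha_prime <- alpha / k_pairwise
  pairs <- utils::combn(nrow(tab), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    sub <- tab[pairs[, j], , drop = FALSE]
    class(sub) <- c("contingency_counts", class(tibble::tibble()))
    res <- run_chosen_test(sub)
    tibble::tibble(model_a = sub$model[1L], model_b = sub$model[2L],
                   method = res$method, statistic = res$statistic,
                   df = res$df, p_value = res$p_value,
                   alpha_prime = alpha_prime,
                   significant = res$p_value < alpha_prime)
  })
  list(omnibus = omnibus, pairwise = do.call(rbind, rows))
}
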