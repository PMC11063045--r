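# Independent brute-force oracles. These deliberately share no code with the
# package: AUC by O(n^2) pair counting, exact tests by full enumeration of
# admissible tables, the 2x2 chi-square by its closed form.

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# two-sided Fisher on a 2x2 by the point-probability rule
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Freeman-Halton on an r x 2 table: enumerate every first-column assignment
# compatible with the margins; multivariate hypergeometric point probability
oracle_freeman_halton <- function(m) {
  row_tot <- rowSums(m)
  c1 <- sum(m[, 1])
  r <- nrow(m)
  tbl_prob <- function(a) exp(sum(lchoose(row_tot, a)) - lchoose(sum(row_tot), c1))
  enumerate <- function(i, remaining) {
    if (i == r) {
      if (remaining <= row_tot[r]) return(list(remaining)) else return(list())
    }
    out <- list()
    for (a in 0:min(row_tot[i], remaining))
      for (rest in enumerate(i + 1, remaining - a))
        out[[length(out) + 1]] <- c(a, rest)
    out
  }
  tables <- enumerate(1, c1)
  p_obs <- tbl_prob(m[, 1])
  total <- 0
  for (a in tables) {
    p <- tbl_prob(a)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

oracle_chi2_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# quick literal record-table builder for metric tests
make_records <- function(true_class, predicted_class,
                         model_name = "m") {
  tibble::tibble(
    record_id = sprintf("R%04d", seq_along(true_class)),
    true_class = true_class,
    predicted_class = predicted_class,
    model_name = model_name
  )
}

published_tables <- function() {
  counts_by_class(fundus_screening_counts())
}
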