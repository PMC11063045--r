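test_that("published omnibus chi-square statistics reproduce from the counts", {
  tabs <- published_tables()
  expect_equal(round_half_up(pearson_chi2(tabs$AMD)$statistic, 2), 21.09)
  expect_equal(round_half_up(pearson_chi2(tabs$DR)$statistic, 2), 68.18)
  expect_equal(round_half_up(pearson_chi2(tabs$normal)$statistic, 2), 143.97)
})

test_that("the 2x2 Pearson statistic equals its closed form, uncorrected", {
  set.seed(88)
  for (i in 1:20) {
    m <- matrix(rpois(4, 40) + 1, 2)
    tab <- contingency_counts(c("a", "b"), m[, 1], rowSums(m))
    expect_equal(pearson_chi2(tab)$statistic, oracle_chi2_2x2(m),
                 tolerance = 1e-9)
  }
  # a continuity-corrected statistic would not reproduce the published 14.28
  amd <- published_tables()$AMD[1:2, ]
  expect_equal(round_half_up(pearson_chi2(amd)$statistic, 2), 14.28)
})

test_that("degenerate tables are handled explicitly", {
  same <- contingency_counts(c("a", "b"), c(50, 50), 100)
  res <- pearson_chi2(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  all_correct <- contingency_counts(c("a", "b"), c(30, 20), c(30, 20))
  expect_error(pearson_chi2(all_correct), "Fisher")
})

test_that("group order never changes a statistic or p-value", {
  tabs <- published_tables()
  for (tab in tabs[c("AMD", "DR")]) {
    flipped <- contingency_counts(rev(tab$model), rev(tab$correct),
                                  rev(tab$correct + tab$incorrect))
    expect_equal(pearson_chi2(flipped)$statistic, pearson_chi2(tab)$statistic)
    expect_equal(pearson_chi2(flipped)$p_value, pearson_chi2(tab)$p_value)
  }
  pm <- tabs$PM
  pm_rev <- contingency_counts(rev(pm$model), rev(pm$correct),
                               rev(pm$correct + pm$incorrect))
  expect_equal(fisher_freeman_halton(pm_rev)$p_value,
               fisher_freeman_halton(pm)$p_value, tolerance = 1e-10)
})

test_that("Fisher 2x2 equals exhaustive hypergeometric enumeration", {
  # spec'd fixed cases
  pm_pair <- contingency_counts(c("RET", "S"), c(151, 90), 151)
  expect_lt(fisher_exact_2x2(pm_pair)$p_value, 0.001)
  forced <- contingency_counts(c("a", "b"), c(1, 0), 1)
  expect_equal(fisher_exact_2x2(forced)$p_value, 1)
  tiny <- contingency_counts(c("a", "b"), c(8, 1), c(10, 6))
  expect_equal(fisher_exact_2x2(tiny)$p_value,
               oracle_fisher_2x2(rbind(c(8, 2), c(1, 5))), tolerance = 1e-7)
  # property: random margins with n <= 200
  set.seed(515)
  for (i in 1:25) {
    tot <- sample(2:100, 2)
    cor <- c(sample(0:tot[1], 1), sample(0:tot[2], 1))
    tab <- contingency_counts(c("a", "b"), cor, tot)
    m <- rbind(c(cor[1], tot[1] - cor[1]), c(cor[2], tot[2] - cor[2]))
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_2x2(m),
                 tolerance = 1e-7)
  }
})

test_that("Freeman-Halton equals exhaustive enumeration on small r x 2 tables", {
  tiny <- contingency_counts(c("a", "b", "c"), c(3, 1, 2), 4)  # n = 12
  expect_equal(fisher_freeman_halton(tiny)$p_value,
               oracle_freeman_halton(rbind(c(3, 1), c(1, 3), c(2, 2))),
               tolerance = 1e-7)
  identical3 <- contingency_counts(c("a", "b", "c"), c(5, 5, 5), 10)
  expect_equal(fisher_freeman_halton(identical3)$p_value, 1, tolerance = 1e-9)
  set.seed(99)
  for (i in 1:5) {
    tot <- sample(3:8, 3, replace = TRUE)
    cor <- vapply(tot, function(t) sample(0:t, 1), integer(1))
    tab <- contingency_counts(c("a", "b", "c"), cor, tot)
    expect_equal(fisher_freeman_halton(tab)$p_value,
                 oracle_freeman_halton(cbind(cor, tot - cor)),
                 tolerance = 1e-7)
  }
  # published PM omnibus: zero cell forces the exact route, p below 0.001
  expect_lt(fisher_freeman_halton(published_tables()$PM)$p_value, 0.001)
})

test_that("the enumeration guard trips on large tables unless Monte Carlo is allowed", {
  big <- contingency_counts(c("a", "b", "c"), c(400, 350, 300), 800)
  expect_error(fisher_freeman_halton(big), "monte_carlo")
  mc1 <- fisher_freeman_halton(big, monte_carlo = TRUE, mc_reps = 2000, seed = 4)
  mc2 <- fisher_freeman_halton(big, monte_carlo = TRUE, mc_reps = 2000, seed = 4)
  expect_identical(mc1$p_value, mc2$p_value)  # seeded, reproducible
  expect_equal(mc1$method, "fisher_exact_mc")
})

test_that("the chi-square / exact selection rule follows expected counts and zero cells", {
  tabs <- published_tables()
  expect_equal(choose_method(tabs$AMD), "pearson_chi2")
  expect_equal(choose_method(tabs$PM), "fisher_exact")   # zero cell
  sy <- contingency_counts(c("S", "Y"), c(90, 109), 151)
  expect_equal(choose_method(sy), "pearson_chi2")
  sparse <- contingency_counts(c("a", "b"), c(19, 17), 20)
  expect_equal(choose_method(sparse), "fisher_exact")    # expected < 5
})

test_that("compare_models runs the omnibus-gated Bonferroni post-hoc procedure", {
  tabs <- published_tables()
  dr <- compare_models(tabs$DR, alpha = 0.05, k_pairwise = 3)
  expect_equal(round_half_up(dr$omnibus$statistic, 2), 68.18)
  expect_true(dr$omnibus$significant)
  pw <- dr$pairwise
  expect_equal(pw$alpha_prime, rep(0.05 / 3, 3))
  ret_y <- pw[pw$model_a == "RETFound" & pw$model_b == "Model Y", ]
  expect_equal(round_half_up(ret_y$statistic, 2), 69.76)
  expect_true(ret_y$significant)
  s_y <- pw[pw$model_a == "Model S", ]
  expect_equal(round_half_up(s_y$statistic, 2), 5.36)
  expect_equal(s_y$p_value, 0.02, tolerance = 0.05)
  expect_false(s_y$significant)  # p ~ 0.02 exceeds alpha' = 0.0167

  spc <- compare_models(tabs$normal, k_pairwise = 3)
  expect_equal(round_half_up(spc$omnibus$statistic, 2), 143.97)

  # identical models: omnibus p = 1, no pairwise tests performed
  flat <- contingency_counts(c("a", "b", "c"), c(40, 40, 40), 100)
  res <- compare_models(flat)
  expect_equal(res$omnibus$p_value, 1)
  expect_equal(nrow(res$pairwise), 0)
})

test_that("mismatched class denominators across models are rejected", {
  bad <- tibble::tibble(model = c("a", "b"), class = "AMD",
                        correct = c(10, 12), total = c(100, 90))
  expect_error(counts_by_class(bad), "denominator")
})

test_that("merging duplicate groups preserves the omnibus conclusion away from the boundary", {
  # three groups, two identical; collapse the duplicates into one
  m3 <- contingency_counts(c("a", "a2", "b"), c(30, 30, 10), 100)
  m2 <- contingency_counts(c("a", "b"), c(60, 10), c(200, 100))
  p3 <- pearson_chi2(m3)$p_value
  p2 <- pearson_chi2(m2)$p_value
  expect_true(p3 < 0.05 && p2 < 0.05)
  flat3 <- contingency_counts(c("a", "a2", "b"), c(30, 30, 30), 100)
  flat2 <- contingency_counts(c("a", "b"), c(60, 30), c(200, 100))
  expect_true(pearson_chi2(flat3)$p_value > 0.9 &&
              pearson_chi2(flat2)$p_value > 0.9)
})
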