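test_that("closed-form net benefit obeys its defining identity and degenerate cases", {
  grid <- seq(0.01, 0.99, by = 0.01)
  # perfect test: no false positives, NB equals the prevalence everywhere
  perfect <- nb_test_closed(1, 1, prevalence = 0.07, p_t = grid)
  expect_equal(perfect$net_benefit, rep(0.07, length(grid)))
  # a test that never refers anyone
  never <- nb_test_closed(0, 1, prevalence = 0.07, p_t = grid)
  expect_equal(never$net_benefit, rep(0, length(grid)))
  # hand-arithmetic oracle at a published operating point
  pt <- nb_test_closed(0.7596, 0.9247, prevalence = 0.05, p_t = 0.10, n = 1e5)
  tp <- 1e5 * 0.05 * 0.7596
  fp <- 1e5 * 0.95 * (1 - 0.9247)
  expect_equal(pt$tp, tp)
  expect_equal(pt$fp, fp)
  expect_equal(pt$net_benefit, tp / 1e5 - (0.10 / 0.90) * fp / 1e5)
  # identity NB = TP/n - w FP/n holds exactly at every emitted point
  cur <- nb_test_closed(0.8, 0.9, 0.05, grid)
  expect_equal(cur$net_benefit,
               cur$tp / cur$n - grid / (1 - grid) * cur$fp / cur$n)
  expect_error(nb_test_closed(0.8, 0.9, 0.05, p_t = 1), "\\(0, 1\\)")
  expect_error(nb_test_closed(0.8, 0.9, 0.05, p_t = 0), "\\(0, 1\\)")
})

test_that("treat-all crosses zero at the prevalence and treat-none is identically zero", {
  expect_equal(nb_treat_all(0.3, p_t = 0.3)$net_benefit, 0)
  expect_equal(nb_treat_all(0.1, p_t = 0.2)$net_benefit, 0.1 - 0.9 * 0.25)
  expect_equal(nb_treat_all(0.1, p_t = 1e-9)$net_benefit, 0.1, tolerance = 1e-7)
  expect_equal(nb_treat_none(c(0.01, 0.5, 0.99))$net_benefit, c(0, 0, 0))
})

test_that("test curves are nonincreasing in the threshold and invariant to cohort size", {
  grid <- seq(0.01, 0.99, by = 0.01)
  cur <- nb_test_closed(0.76, 0.92, 0.03, grid)
  expect_true(all(diff(cur$net_benefit) <= 0))
  small <- nb_test_closed(0.76, 0.92, 0.03, grid, n = 500)
  expect_equal(small$net_benefit, cur$net_benefit)
})

test_that("net benefit increases with prevalence at any fixed threshold", {
  grid <- seq(0.05, 0.95, by = 0.05)
  urban <- nb_test_closed(0.76, 0.92, prevalence = 0.054, p_t = grid)
  rural <- nb_test_closed(0.76, 0.92, prevalence = 0.037, p_t = grid)
  expect_true(all(urban$net_benefit > rural$net_benefit))
})

test_that("combined screening reduces correctly and weights sensitivity by prevalence", {
  one <- combined_screening(c(AMD = 0.76), c(AMD = 0.05), spec = 0.92)
  expect_equal(one, list(sens = 0.76, spec = 0.92, prevalence = 0.05))
  two <- combined_screening(c(a = 0.8, b = 0.6), c(a = 0.02, b = 0.02), 0.9)
  expect_equal(two$sens, 0.7)
  expect_equal(two$prevalence, 0.04)
  # published operating points, hand-arithmetic weighted mean
  sens <- c(AMD = 218 / 287, DR = 321 / 337, PM = 151 / 151)
  prev <- c(AMD = 0.05, DR = 0.03, PM = 0.01)
  cmb <- combined_screening(sens, prev, spec = 1031 / 1115)
  expect_equal(cmb$sens, sum(prev * sens) / sum(prev))
  expect_equal(cmb$spec, 1031 / 1115)
  expect_error(combined_screening(numeric(), numeric(), 0.9), "empty")
})

test_that("empirical net benefit counts true and false screen-positives", {
  recs <- make_records(
    true_class = c("AMD", "AMD", "DR", "normal", "normal"),
    predicted_class = c("AMD", "normal", "DR", "normal", "AMD"))
  nb <- nb_empirical(recs, p_t = 0.2)
  expect_equal(c(nb$tp, nb$fp, nb$n), c(2, 1, 5))
  expect_equal(nb$net_benefit, 2 / 5 - 0.25 * 1 / 5)
  exact <- nb_empirical(recs, p_t = 0.2, positive_rule = "exact_class",
                        disease = "AMD")
  expect_equal(c(exact$tp, exact$fp), c(1, 1))
  # perfect predictions: NB equals the observed disease fraction at any p_t
  perfect <- make_records(c("AMD", "DR", "normal", "normal"),
                          c("AMD", "DR", "normal", "normal"))
  expect_equal(nb_empirical(perfect, 0.37)$net_benefit, 0.5)
  # no diseased records and perfect specificity: zero
  clean <- make_records(rep("normal", 10), rep("normal", 10))
  expect_equal(nb_empirical(clean, 0.1)$net_benefit, 0)
  expect_error(nb_empirical(perfect[0, ], 0.1), "empty")
})

test_that("closed-form and record-level net benefit agree on a simulated cohort", {
  spec <- cohort_spec(c("AMD", "DR", "PM"),
                      c(AMD = 0.026, DR = 0.018, PM = 0.010), 100000, "urban")
  clf <- classifier_spec(c(AMD = 218 / 287, DR = 321 / 337, PM = 1),
                         specificity = 1031 / 1115)
  recs <- simulate_cohort(spec, clf, seed = 77)
  cmb <- combined_screening(clf$sensitivity, spec$prevalence, clf$specificity)
  grid <- seq(0.01, 0.99, by = 0.01)
  closed <- nb_test_closed(cmb$sens, cmb$spec, cmb$prevalence, grid)
  emp <- nb_empirical(recs, grid)
  # binomial error on TP/n and FP/n rates, propagated through the identity
  n <- spec$size
  p_tp <- cmb$prevalence * cmb$sens
  p_fp <- (1 - cmb$prevalence) * (1 - cmb$spec)
  w <- grid / (1 - grid)
  tol <- 4 * sqrt(p_tp * (1 - p_tp) / n + w^2 * p_fp * (1 - p_fp) / n)
  expect_true(all(abs(emp$net_benefit - closed$net_benefit) < tol))
})

test_that("build_curves assembles every strategy on the shared grid", {
  models <- list(RET = list(sens = 0.76, spec = 0.92),
                 S = list(sens = 0.61, spec = 0.78))
  cur <- build_curves(models, prevalence = 0.05, setting_label = "urban")
  expect_setequal(unique(cur$strategy), c("RET", "S", "treat_all", "treat_none"))
  expect_equal(nrow(cur), 4 * 99)
  ta <- cur[cur$strategy == "treat_all", ]
  expect_equal(ta$net_benefit,
               0.05 - 0.95 * ta$threshold / (1 - ta$threshold))
  # sens = spec = 1 dominates treat-all strictly at every positive threshold
  ideal <- build_curves(list(ideal = list(sens = 1, spec = 1)), 0.05)
  nb_ideal <- ideal$net_benefit[ideal$strategy == "ideal"]
  nb_all <- ideal$net_benefit[ideal$strategy == "treat_all"]
  expect_true(all(nb_ideal > nb_all))
  expect_error(build_curves(models, 0.05, thresholds = c(0, 0.5)), "\\(0, 1\\)")
  expect_error(build_curves(models, 0.05, thresholds = c(0.5, 0.2)),
               "increasing")
})

test_that("dominance intervals match a brute-force grid scan", {
  grid <- seq(0.01, 0.99, by = 0.01)
  mk <- function(strategy, nb) tibble::tibble(
    setting = "x", strategy = strategy, threshold = grid,
    tp = 0, fp = 0, n = 1, net_benefit = nb)
  # one strategy strictly above: single interval spanning the grid
  cur <- rbind(mk("hi", rep(1, 99)), mk("lo", rep(0, 99)))
  dom <- dominance_intervals(cur)
  expect_equal(nrow(dom), 1)
  expect_equal(c(dom$lower, dom$upper), c(0.01, 0.99))
  # identical curves: no single maximiser anywhere
  expect_equal(nrow(dominance_intervals(rbind(mk("a", rep(1, 99)),
                                              mk("b", rep(1, 99))))), 0)
  # curves crossing at a known grid point, with a tie exactly there
  a <- 0.5 - 0.5 * grid
  b <- rep(0.3, 99)
  a[40] <- b[40]  # exact tie at threshold 0.40
  dom <- dominance_intervals(rbind(mk("a", a), mk("b", b)))
  # brute-force oracle over the grid
  top <- ifelse(a > b, "a", ifelse(b > a, "b", NA))
  expect_equal(dom[dom$strategy == "a", ]$upper, max(grid[which(top == "a")]))
  expect_equal(dom[dom$strategy == "b", ]$lower, min(grid[which(top == "b")]))
  expect_false(any(dom$lower <= 0.4 & dom$upper >= 0.4))  # tie at 0.40 excluded
  # mismatched grids are an error
  bad <- rbind(mk("a", a),
               tibble::tibble(setting = "x", strategy = "b",
                              threshold = grid + 0.001, tp = 0, fp = 0, n = 1,
                              net_benefit = b))
  expect_error(dominance_intervals(bad), "shared")
})
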