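test_that("cross-product odds ratios reproduce the univariate estimates", {
  expect_equal(odds_ratio(tab_fever())$or, 12 * 70 / (11 * 14))
  expect_equal(round(odds_ratio(tab_fever())$or, 1), 5.5)
  expect_equal(round(odds_ratio(tab_hypoxemia())$or, 1), 3.2)
  # symmetric table
  expect_equal(odds_ratio(two_by_two(7, 7, 7, 7))$or, 1)
})

test_that("odds ratio is symmetric under transposition and flags zero cells", {
  t <- tab_hypoxemia()
  transposed <- two_by_two(t$a, t$c, t$b, t$d)
  expect_equal(odds_ratio(t)$or, odds_ratio(transposed)$or)
  corrected <- odds_ratio(two_by_two(0, 19, 26, 62))
  expect_true(corrected$corrected)
  expect_equal(corrected$or, (0.5 * 62.5) / (19.5 * 26.5))
  expect_error(odds_ratio(two_by_two(0, 0, 26, 62)), "undefined")
})

test_that("odds ratio agrees with the univariate logistic coefficient", {
  coh <- generate_cohort(synthetic_config(seed = 13))
  s <- dichotomize(coh)
  t <- two_by_two(sum(s$fever_temp == 1 & s$cxr_positive == 1),
                  sum(s$fever_temp == 1 & s$cxr_positive == 0),
                  sum(s$fever_temp == 0 & s$cxr_positive == 1),
                  sum(s$fever_temp == 0 & s$cxr_positive == 0))
  fit <- fit_logistic(s$cxr_positive, s[, "fever_temp", drop = FALSE])
  expect_equal(fit$or[["fever_temp"]], odds_ratio(t)$or, tolerance = 1e-6)
})

test_that("Yates-corrected chi-squared reproduces the group-test p-values", {
  expect_equal(chi2_test(tab_fever())$p_value, 0.0012, tolerance = 0.05)
  expect_equal(chi2_test(tab_hypoxemia())$p_value, 0.024, tolerance = 0.02)
  # identical row distributions: no association
  flat <- chi2_test(two_by_two(10, 20, 5, 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # invariant to swapping the table's rows and columns
  t <- tab_tachypnea()
  expect_equal(chi2_test(t)$statistic,
               chi2_test(two_by_two(t$a, t$c, t$b, t$d))$statistic)
  expect_error(chi2_test(two_by_two(0, 0, 5, 7)), "zero margin")
})

test_that("Fisher's exact test matches brute-force enumeration", {
  expect_equal(fisher_exact(tab_asthma())$p_value, fisher_enum(tab_asthma()))
  expect_equal(round(fisher_exact(tab_asthma())$p_value, 3), 0.006)
  expect_equal(fisher_exact(two_by_two(2, 3, 4, 1))$p_value,
               fisher_enum(two_by_two(2, 3, 4, 1)))
  # zero margin admits a single table
  expect_equal(fisher_exact(two_by_two(0, 0, 5, 9))$p_value, 1)
  set.seed(20)
  for (i in 1:200) {
    t <- random_table(40)
    expect_equal(fisher_exact(t)$p_value, fisher_enum(t), tolerance = 1e-10,
                 label = sprintf("table (%d,%d,%d,%d)", t$a, t$b, t$c, t$d))
  }
})

test_that("the test chooser uses Fisher below the expected-count threshold", {
  expect_equal(group_test(tab_fever())$test, "chi-squared")
  expect_equal(group_test(tab_asthma())$test, "fisher")
  copd <- two_by_two(3, 5, 23, 76)
  expect_equal(group_test(copd)$test, "fisher")
  expect_equal(round(group_test(copd)$p_value, 3), 0.399)
})

test_that("logistic fits refuse degenerate inputs with diagnostics", {
  x <- data.frame(a = rbinom(40, 1, 0.5))
  expect_error(fit_logistic(rep(0, 40), x), "constant")
  expect_error(fit_logistic(rbinom(40, 1, 0.5), data.frame(a = rep(1, 40))),
               "constant predictor")
  # perfectly separated outcome
  sep <- data.frame(a = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(sep$a, sep), "separation")
})

test_that("AIC and odds-ratio bookkeeping are internally consistent", {
  coh <- generate_cohort(synthetic_config(seed = 19))
  s <- dichotomize(coh)
  fit <- fit_logistic(s$cxr_positive, s[, analysis_signs()])
  expect_equal(fit$aic, 2 * length(fit$coef) - 2 * fit$loglik)
  expect_equal(fit$or, exp(fit$coef))
  expect_equal(fit$n, 107)
})

test_that("backward selection keeps truly predictive terms", {
  # two strong predictors, three null ones, a single realization
  fx <- logistic_recovery_fixture(5000, -2, c(fever_temp = log(5),
                                              hypoxemia = log(2.9)),
                                  seed = 55)
  s <- dichotomize(fx$cohort)
  sel <- backward_select_aic(s$cxr_positive, s[, analysis_signs()])
  expect_true(all(c("fever_temp", "hypoxemia") %in% sel$selected))
  # agrees with the reference stepwise implementation on the same data
  skip_if_not_installed("MASS")
  dat <- cbind(y = s$cxr_positive, s[, analysis_signs()])
  full <- stats::glm(y ~ ., data = dat, family = stats::binomial())
  ref <- MASS::stepAIC(full, direction = "backward", trace = 0)
  expect_setequal(sel$selected,
                  setdiff(names(stats::coef(ref)), "(Intercept)"))
})

test_that("selection retains both true terms across replicates", {
  # AIC keeps a null term with probability P(chisq_1 > 2) ~ 0.157, so the
  # exact two-term set appears in only ~60% of replicates; the true terms
  # themselves should essentially never be dropped at this effect size
  both <- 0L
  exact <- 0L
  for (i in 1:50) {
    fx <- logistic_recovery_fixture(5000, -2, c(fever_temp = log(5),
                                                hypoxemia = log(2.9)),
                                    seed = 1000 + i)
    s <- dichotomize(fx$cohort)
    sel <- backward_select_aic(s$cxr_positive, s[, analysis_signs()])
    if (all(c("fever_temp", "hypoxemia") %in% sel$selected)) both <- both + 1L
    if (setequal(sel$selected, c("fever_temp", "hypoxemia"))) exact <- exact + 1L
  }
  expect_gte(both, 45L)    # >= 90% of replicates
  expect_gte(exact, 20L)   # modal outcome, ~60% expected
})

test_that("selection stops when no deletion lowers the AIC, and traces it", {
  fx <- logistic_recovery_fixture(2000, -1.5, c(fever_temp = log(6),
                                                hypoxemia = log(4)),
                                  seed = 77)
  s <- dichotomize(fx$cohort)
  sel <- backward_select_aic(s$cxr_positive, s[, c("fever_temp", "hypoxemia")])
  expect_setequal(sel$selected, c("fever_temp", "hypoxemia"))
  # AIC strictly decreases along the taken path
  taken <- sel$trace$aic[sel$trace$taken]
  expect_true(all(diff(taken) < 0) || length(taken) == 1)
  # every candidate deletion is recorded at every step
  expect_true(all(table(sel$trace$step[-1]) > 0))
})

test_that("AIC ties are broken by canonical column order", {
  # x2 duplicates x1 except on row pairs swapped within outcome classes, so
  # the models {x1} and {x2} have identical sufficient statistics and their
  # deletion AICs tie to machine precision
  y <- rep(c(0, 1), each = 30)
  x1 <- c(rep(c(0, 1), 15), rep(c(1, 0, 1), 10))
  x2 <- x1
  swap <- function(v, i, j) { v[c(i, j)] <- v[c(j, i)]; v }
  x2 <- swap(x2, 1, 2)    # y equal on both rows, x1 values 0,1
  x2 <- swap(x2, 31, 32)
  x <- data.frame(x1 = x1, x2 = x2)
  sel <- backward_select_aic(y, x)
  expect_equal(sel$selected, "x2")  # x1, earlier in column order, dropped
})
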