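test_that("the performance panel reproduces the published rule metrics", {
  p <- performance_panel(ev_two_sign())
  expect_equal(p$sensitivity$estimate, 18 / 26)
  expect_equal(p$specificity$estimate, 56 / 81)
  expect_equal(p$npv$estimate, 56 / 64)
  expect_equal(p$accuracy$estimate, 74 / 107)
  expect_equal(p$lr_neg$estimate, (8 / 26) / (56 / 81))
  expect_equal(round(p$lr_neg$estimate, 2), 0.45)
  expect_equal(round(p$auroc$estimate, 2), 0.69)

  m <- performance_panel(ev_marchello())
  expect_equal(round(m$sensitivity$estimate, 3), 0.923)
  expect_equal(round(m$specificity$estimate, 2), 0.21)
  expect_equal(round(m$lr_neg$estimate, 2), 0.37)
  expect_equal(round(m$auroc$estimate, 2), 0.57)

  e <- performance_panel(ev_marchello_spo2())
  expect_equal(round(e$sensitivity$estimate, 2), 0.96)
  expect_equal(round(e$npv$estimate, 2), 0.94)
  expect_equal(round(e$lr_neg$estimate, 2), 0.21)
})

test_that("a perfect rule has unit metrics and zero negative LR", {
  p <- performance_panel(rule_evaluation_from_counts(20, 0, 0, 30, "perfect"))
  expect_equal(p$sensitivity$estimate, 1)
  expect_equal(p$specificity$estimate, 1)
  expect_equal(p$accuracy$estimate, 1)
  expect_equal(p$auroc$estimate, 1)
  expect_equal(p$lr_neg$estimate, 0)
  expect_true(is_undefined(p$lr_pos))  # specificity 1: no false positives
})

test_that("empty outcome margins are refused and zero denominators tagged", {
  expect_error(performance_panel(rule_evaluation_from_counts(0, 25, 0, 56)),
               "no diseased")
  expect_error(performance_panel(rule_evaluation_from_counts(18, 0, 8, 0)),
               "no non-diseased")
  never_pos <- performance_panel(rule_evaluation_from_counts(0, 0, 26, 81))
  expect_true(is_undefined(never_pos$ppv))
  expect_false(is_undefined(never_pos$npv))
  spec_zero <- performance_panel(rule_evaluation_from_counts(26, 81, 0, 0))
  expect_true(is_undefined(spec_zero$lr_neg))
  expect_match(format(spec_zero$lr_neg), "—")
})

test_that("Clopper-Pearson intervals match the beta/binomial duality", {
  ci <- proportion_ci(18, 26)
  expect_equal(round(ci$lower, 2), 0.48)
  expect_equal(round(ci$upper, 2), 0.86)
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 1)
  # oracle: binom.test's exact interval
  for (kn in list(c(5, 20), c(0, 7), c(7, 7), c(1, 50), c(33, 40))) {
    ours <- proportion_ci(kn[1], kn[2])
    ref <- stats::binom.test(kn[1], kn[2])$conf.int
    expect_equal(c(ours$lower, ours$upper), as.numeric(ref), tolerance = 1e-10,
                 label = sprintf("k=%d n=%d", kn[1], kn[2]))
  }
})

test_that("interval widths bracket the estimate and shrink with n", {
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- proportion_ci(n * 0.2, n)
    expect_lte(ci$lower, 0.2)
    expect_gte(ci$upper, 0.2)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("likelihood-ratio intervals use the Simel log method", {
  lrn <- lr_ci(ev_two_sign(), "neg")
  expect_equal(round(c(lrn$lower, lrn$upper), 2), c(0.25, 0.81))
  lrp <- lr_ci(ev_two_sign(), "pos")
  expect_equal(round(lrp$estimate, 2), 2.24)
  expect_equal(round(c(lrp$lower, lrp$upper), 2), c(1.48, 3.40))
  # the extended rule's single false negative gives a wide interval
  wide <- lr_ci(ev_marchello_spo2(), "neg")
  expect_equal(round(wide$estimate, 2), 0.21)
  expect_gt(wide$upper / wide$lower, 10)
  # LR+ of a useless rule is 1
  useless <- rule_evaluation_from_counts(13, 40, 13, 41)
  expect_equal(lr_ci(useless, "pos")$estimate, (13 / 26) / (40 / 81))
  coin <- rule_evaluation_from_counts(13, 40, 13, 40)
  expect_equal(lr_ci(coin, "pos")$estimate, 1)
  # undefined markers for empty defining cells
  expect_true(is_undefined(lr_ci(rule_evaluation_from_counts(26, 81, 0, 0),
                                 "neg")))
})

test_that("binary AUROC is the sens/spec average with a DeLong interval", {
  a <- binary_auroc(ev_two_sign())
  expect_equal(a$estimate, (18 / 26 + 56 / 81) / 2)
  expect_equal(round(c(a$lower, a$upper), 2), c(0.59, 0.80))
  expect_equal(round(binary_auroc(ev_marchello())$estimate, 2), 0.57)
  # coin rule
  coin <- rule_evaluation_from_counts(13, 40, 13, 40)
  expect_equal(binary_auroc(coin)$estimate, 0.5)
  # invariant to swapping sensitivity and specificity
  swapped <- rule_evaluation_from_counts(56, 8, 25, 18)
  expect_equal(binary_auroc(swapped)$estimate, binary_auroc(ev_two_sign())$estimate)
})

test_that("identities hold on random tables: Bayes PPV and LR-/spec", {
  set.seed(33)
  for (i in 1:50) {
    t <- random_table(200)
    if (t$a + t$c == 0 || t$b + t$d == 0) next
    ev <- rule_evaluation_from_counts(t$a, t$b, t$c, t$d)
    p <- performance_panel(ev)
    sens <- p$sensitivity$estimate
    spec <- p$specificity$estimate
    prev <- (t$a + t$c) / (t$a + t$b + t$c + t$d)
    if (!is_undefined(p$ppv) && t$a + t$b > 0) {
      odds_ppv <- prev * sens / (prev * sens + (1 - prev) * (1 - spec))
      expect_equal(p$ppv$estimate, odds_ppv, tolerance = 1e-12)
    }
    if (!is_undefined(p$lr_neg) && spec > 0)
      expect_equal(p$lr_neg$estimate, (1 - sens) / spec, tolerance = 1e-15)
  }
})

test_that("post-test probability follows the odds form", {
  low <- post_test_probability(26 / 107, 0.445)
  expect_equal(round(low$posttest, 3), 0.125)
  lower <- post_test_probability(26 / 107, 0.208)
  expect_equal(round(lower$posttest, 3), 0.063)
  expect_equal(post_test_probability(0.3, 1)$posttest, 0.3)
  expect_error(post_test_probability(0, 0.5), "strictly between")
  expect_error(post_test_probability(0.2, -1), ">= 0")
})
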