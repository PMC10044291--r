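# Diagnostic performance of a binary rule against the reference standard:
# sensitivity/specificity/accuracy/predictive values with Clopper-Pearson
# exact intervals, likelihood ratios with Simel log-method intervals, the
# binary-rule AUROC with its DeLong-form interval, and post-test
# probability arithmetic.
#
# Zero denominators yield a tagged "undefined" metric that renders as an
# em dash in reports, never NaN arithmetic.

dx_metric <- function(estimate, lower = NA_real_, upper = NA_real_,
                      undefined = FALSE, reason = NULL) {
  structure(list(estimate = if (undefined) NA_real_ else estimate,
                 lower = lower, upper = upper,
                 undefined = undefined, reason = reason),
            class = "dx_metric")
}

#' Is a diagnostic metric undefined?
#'
#' @param m A metric as returned inside a [performance_panel()].
#' @return `TRUE` when the metric's denominator was degenerate.
#' @export
is_undefined <- function(m) inherits(m, "dx_metric") && isTRUE(m$undefined)

#' @export
format.dx_metric <- function(x, digits = 2, ...) {
  if (x$undefined) return(paste0("— (", x$reason, ")"))
  if (is.na(x$lower)) return(formatC(x$estimate, digits = digits, format = "f"))
  sprintf("%s [%s, %s]", formatC(x$estimate, digits = digits, format = "f"),
          formatC(x$lower, digits = digits, format = "f"),
          formatC(x$upper, digits = digits, format = "f"))
}

#' @export
print.dx_metric <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta quantiles: the lower bound is the
#' `alpha/2` quantile of `Beta(k, n - k + 1)` (0 when `k = 0`), the upper
#' the `1 - alpha/2` quantile of `Beta(k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level.
#' @return List with `estimate`, `lower`, `upper`.
#' @examples
#' proportion_ci(18, 26)  # sensitivity 69% [0.48, 0.86]
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  alpha <- 1 - level
  list(estimate = k / n,
       lower = if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1),
       upper = if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k))
}

prop_metric <- function(k, n, level, what) {
  if (n == 0) return(dx_metric(undefined = TRUE,
                               reason = paste0("no ", what, " denominator")))
  ci <- proportion_ci(k, n, level)
  dx_metric(ci$estimate, ci$lower, ci$upper)
}

#' Likelihood-ratio confidence interval (Simel log method)
#'
#' Interval `exp(log LR +/- z * SE)` with the Simel standard error on the
#' log scale; for LR- this is
#' `sqrt(1/FN - 1/(TP+FN) + 1/TN - 1/(TN+FP))`, and symmetrically for LR+.
#' A zero defining cell leaves the interval undefined.
#'
#' @param ev A `rule_evaluation` (see [evaluate_rule()]).
#' @param which `"pos"` or `"neg"`.
#' @param level Confidence level.
#' @return A metric list with `estimate`, `lower`, `upper` (or an undefined
#'   marker with its reason).
#' @export
lr_ci <- function(ev, which = c("neg", "pos"), level = 0.95) {
  which <- match.arg(which)
  t <- ev$table
  tp <- t$a; fp <- t$b; fn <- t$c; tn <- t$d
  z <- qnorm(1 - (1 - level) / 2)
  if (which == "neg") {
    if (tn == 0) return(dx_metric(undefined = TRUE, reason = "specificity is 0"))
    est <- (fn / (tp + fn)) / (tn / (tn + fp))
    if (fn == 0)
      return(dx_metric(0, undefined = FALSE))  # LR- exactly 0, no log-scale CI
    se <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (tn + fp))
  } else {
    if (fp == 0)
      return(dx_metric(undefined = TRUE, reason = "specificity is 1"))
    if (tp == 0) return(dx_metric(0, undefined = FALSE))
    est <- (tp / (tp + fn)) / (fp / (tn + fp))
    se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (tn + fp))
  }
  dx_metric(est, est * exp(-z * se), est * exp(z * se))
}

#' AUROC of a single binary rule
#'
#' For a binary test the ROC curve has a single interior point, so the area
#' is `(sensitivity + specificity) / 2`. The confidence interval uses the
#' DeLong small-sample variance
#' `sens(1-sens)/(4(n+ - 1)) + spec(1-spec)/(4(n- - 1))` with a normal
#' quantile.
#'
#' @param ev A `rule_evaluation`.
#' @param level Confidence level.
#' @return A metric list with `estimate`, `lower`, `upper`.
#' @export
binary_auroc <- function(ev, level = 0.95) {
  t <- ev$table
  npos <- t$a + t$c
  nneg <- t$b + t$d
  if (npos < 2 || nneg < 2)
    return(dx_metric(undefined = TRUE,
                     reason = "need at least 2 diseased and 2 non-diseased"))
  sens <- t$a / npos
  spec <- t$d / nneg
  est <- (sens + spec) / 2
  se <- sqrt(sens * (1 - sens) / (npos - 1) +
             spec * (1 - spec) / (nneg - 1)) / 2
  z <- qnorm(1 - (1 - level) / 2)
  dx_metric(est, max(0, est - z * se), min(1, est + z * se))
}

#' Full diagnostic performance panel for a rule evaluation
#'
#' Point estimates are the usual 2x2 ratios (sens = TP/(TP+FN), spec =
#' TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/N,
#' LR+ = sens/(1-spec), LR- = (1-sens)/spec, AUROC = (sens+spec)/2).
#' Proportions carry Clopper-Pearson exact intervals, likelihood ratios
#' Simel log-method intervals, the AUROC its DeLong-form interval. Zero
#' denominators give tagged undefined metrics.
#'
#' @param ev A `rule_evaluation` from [evaluate_rule()] or
#'   [rule_evaluation_from_counts()]. Both diseased and non-diseased margins
#'   must be non-empty.
#' @param level Confidence level.
#' @return A `performance_panel` object with metrics `sensitivity`,
#'   `specificity`, `accuracy`, `npv`, `ppv`, `lr_pos`, `lr_neg`, `auroc`,
#'   plus `n_rule_positive`, `prevented_tests`, `missed_cases`, `n` and the
#'   source evaluation.
#' @examples
#' ev <- rule_evaluation_from_counts(18, 25, 8, 56, "fever or hypoxemia")
#' performance_panel(ev)
#' @export
performance_panel <- function(ev, level = 0.95) {
  stopifnot(inherits(ev, "rule_evaluation"))
  t <- ev$table
  tp <- t$a; fp <- t$b; fn <- t$c; tn <- t$d
  n <- tp + fp + fn + tn
  if (tp + fn == 0) stop("no diseased patients: sensitivity margin is empty")
  if (fp + tn == 0) stop("no non-diseased patients: specificity margin is empty")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(
    rule_name = ev$rule$name,
    sensitivity = prop_metric(tp, tp + fn, level, "diseased"),
    specificity = prop_metric(tn, tn + fp, level, "non-diseased"),
    accuracy = prop_metric(tp + tn, n, level, "cohort"),
    npv = prop_metric(tn, tn + fn, level, "rule-negative"),
    ppv = prop_metric(tp, tp + fp, level, "rule-positive"),
    lr_neg = if (spec == 0)
      dx_metric(undefined = TRUE, reason = "specificity is 0")
      else lr_ci(ev, "neg", level),
    lr_pos = if (spec == 1)
      dx_metric(undefined = TRUE, reason = "specificity is 1")
      else lr_ci(ev, "pos", level),
    auroc = binary_auroc(ev, level),
    n = n, n_rule_positive = ev$n_rule_positive,
    prevented_tests = ev$prevented_tests, missed_cases = ev$missed_cases,
    evaluation = ev, level = level
  ), class = "performance_panel")
}

#' @export
print.performance_panel <- function(x, ...) {
  cat("<performance_panel> ", x$rule_name, sprintf(" (N = %d)\n", x$n), sep = "")
  for (nm in c("sensitivity", "specificity", "accuracy", "npv", "ppv",
               "lr_neg", "lr_pos", "auroc"))
    cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  rule-positive %d (%d%%); prevented X-rays %d (%d%%); missed %d\n",
              x$n_rule_positive, round(100 * x$n_rule_positive / x$n),
              x$prevented_tests, round(100 * x$prevented_tests / x$n),
              x$missed_cases))
  invisible(x)
}

#' Post-test probability after applying a likelihood ratio
#'
#' Converts the pre-test probability to odds, multiplies by the likelihood
#' ratio, and converts back:
#' `post = (pre/(1-pre) * LR) / (1 + pre/(1-pre) * LR)`.
#'
#' @param pretest Pre-test probability, strictly between 0 and 1.
#' @param lr Likelihood ratio (>= 0); use the LR- of a rule to obtain the
#'   probability of disease after a negative rule.
#' @return List with `pretest`, `lr`, `posttest`.
#' @examples
#' post_test_probability(26 / 107, 0.445)  # 24% -> 12%
#' @export
post_test_probability <- function(pretest, lr) {
  if (!is.finite(pretest) || pretest <= 0 || pretest >= 1)
    stop("pretest probability must lie strictly between 0 and 1")
  if (!is.finite(lr) || lr < 0) stop("likelihood ratio must be >= 0")
  odds <- pretest / (1 - pretest) * lr
  list(pretest = pretest, lr = lr, posttest = odds / (1 + odds))
}
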