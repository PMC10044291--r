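# Paired comparison of two decision rules on the same cohort (difference in
# sensitivity, ratio of negative likelihood ratios) and inter-rater
# agreement statistics (Cohen's kappa, specific agreement).

#' Paired classification counts for two rules
#'
#' Cross-classification of two rules, A and B, applied to the same
#' patients, split by disease status. Within each block the four counts are
#' `n11` (both rules positive), `n10` (A positive only), `n01` (B positive
#' only) and `n00` (neither positive).
#'
#' @param diseased,nondiseased Numeric vectors `c(n11, n10, n01, n00)` of
#'   paired counts among diseased and non-diseased patients.
#' @param rule_a,rule_b Rule names for labeling.
#' @return A `paired_counts` object with recoverable marginal sensitivities
#'   and specificities.
#' @export
paired_counts <- function(diseased, nondiseased = c(0, 0, 0, 0),
                          rule_a = "A", rule_b = "B") {
  check <- function(x, what) {
    if (length(x) != 4L || any(!is.finite(x)) || any(x < 0) ||
        any(x != round(x)))
      stop(what, " must be four non-negative integer counts (n11,n10,n01,n00)")
  }
  check(diseased, "diseased")
  check(nondiseased, "nondiseased")
  structure(list(diseased = setNames(as.numeric(diseased),
                                     c("n11", "n10", "n01", "n00")),
                 nondiseased = setNames(as.numeric(nondiseased),
                                        c("n11", "n10", "n01", "n00")),
                 rule_a = rule_a, rule_b = rule_b),
            class = "paired_counts")
}

#' Cross-classify two rules on a cohort
#'
#' Evaluates both rules patientwise and assembles the [paired_counts()]
#' blocks needed for paired comparisons.
#'
#' @param rule_a,rule_b [decision_rule()] objects, built-in rule names, or
#'   rule expression strings (as accepted by [evaluate_rule()]).
#' @param cohort A cohort data.frame, complete-case for all referenced
#'   signs and the outcome.
#' @param cutoffs Cut-offs used when `cohort` holds raw fields.
#' @return A `paired_counts` object.
#' @export
pair_rules <- function(rule_a, rule_b, cohort, cutoffs = default_cutoffs()) {
  as_rule <- function(r) {
    if (is.character(r) && length(r) == 1L) {
      registry <- builtin_rules()
      r <- if (r %in% names(registry)) registry[[r]] else decision_rule(r, r)
    }
    stopifnot(inherits(r, "decision_rule"))
    r
  }
  rule_a <- as_rule(rule_a)
  rule_b <- as_rule(rule_b)
  # evaluate_rule enforces the complete-case precondition per rule
  evaluate_rule(rule_a, cohort, cutoffs)
  evaluate_rule(rule_b, cohort, cutoffs)
  signs <- if (!"temperature" %in% names(cohort) &&
               "cxr_positive" %in% names(cohort))
    cohort else dichotomize(cohort, cutoffs)
  pa <- eval_tree(rule_a$tree, signs)
  pb <- eval_tree(rule_b$tree, signs)
  d <- signs$cxr_positive
  block <- function(status) {
    c(sum(pa == 1 & pb == 1 & d == status), sum(pa == 1 & pb == 0 & d == status),
      sum(pa == 0 & pb == 1 & d == status), sum(pa == 0 & pb == 0 & d == status))
  }
  paired_counts(block(1), block(0), rule_a$name, rule_b$name)
}

#' Paired difference in sensitivity between two rules
#'
#' Point estimate is the difference of marginal sensitivities,
#' `sens(B) - sens(A)`, computed from the paired counts among diseased
#' patients. The confidence interval is a Wald interval on the paired
#' difference with a Laplace adjustment (1 added to each of the four paired
#' cells before computing the adjusted difference and its variance), after
#' Bonett and Price. The adjustment affects only the interval, never the
#' point estimate.
#'
#' @param paired A [paired_counts()] object with a non-empty diseased block.
#' @param level Confidence level.
#' @return List with `difference`, `sens_a`, `sens_b`, `lower`, `upper`,
#'   `significant` (interval excludes 0).
#' @examples
#' # two-sign rule (A) vs the four-sign meta-analysis rule (B)
#' compare_sensitivity(paired_counts(diseased = c(17, 1, 7, 1)))
#' @export
compare_sensitivity <- function(paired, level = 0.95) {
  stopifnot(inherits(paired, "paired_counts"))
  s <- sum(paired$diseased)
  if (s == 0) stop("no diseased patients: sensitivity difference undefined")
  n <- paired$diseased
  sens_a <- (n[["n11"]] + n[["n10"]]) / s
  sens_b <- (n[["n11"]] + n[["n01"]]) / s
  adj <- n + 1
  ns <- s + 4
  diff_adj <- (adj[["n01"]] - adj[["n10"]]) / ns
  var_adj <- (adj[["n01"]] + adj[["n10"]] -
                (adj[["n01"]] - adj[["n10"]])^2 / ns) / ns^2
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(var_adj)
  lo <- max(-1, diff_adj - half)
  hi <- min(1, diff_adj + half)
  list(difference = sens_b - sens_a, sens_a = sens_a, sens_b = sens_b,
       lower = lo, upper = hi, significant = lo > 0 || hi < 0)
}

#' Ratio of negative likelihood ratios between two paired rules
#'
#' Point estimate is `LR-(B) / LR-(A)` from the marginal sensitivities and
#' specificities. The default interval is on the log scale by the delta
#' method with the multinomial covariance of the paired cells (the two
#' blocks are independent multinomials; within a block the two rules'
#' negative proportions co-vary through the both-negative cell). The
#' `"raw"` scale applies the same delta-method standard error to the
#' untransformed ratio, giving an additive Wald interval that may cross
#' zero.
#'
#' @param paired A [paired_counts()] object; both blocks must be non-empty
#'   and both rules' LR- defined (non-zero false-negative and specificity
#'   denominators for the interval).
#' @param level Confidence level.
#' @param scale `"log"` (default) or `"raw"`.
#' @return List with `ratio`, `lr_neg_a`, `lr_neg_b`, `lower`, `upper`,
#'   `se_log`, `scale`, `significant` (interval excludes 1). When a
#'   defining cell is zero the interval is `NA` with an explanatory
#'   `reason`.
#' @export
compare_lr_neg <- function(paired, level = 0.95, scale = c("log", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(paired, "paired_counts"))
  s <- sum(paired$diseased)
  r <- sum(paired$nondiseased)
  if (s == 0 || r == 0)
    stop("both diseased and non-diseased blocks must be non-empty")
  nd <- paired$diseased
  nn <- paired$nondiseased
  # per-rule negative proportions: among diseased = 1 - sens, among
  # non-diseased = specificity
  pa <- (nd[["n01"]] + nd[["n00"]]) / s
  pb <- (nd[["n10"]] + nd[["n00"]]) / s
  qa <- (nn[["n01"]] + nn[["n00"]]) / r
  qb <- (nn[["n10"]] + nn[["n00"]]) / r
  if (qa == 0 || qb == 0)
    stop("LR- undefined: a rule has specificity 0 on these counts")
  lr_a <- pa / qa
  lr_b <- pb / qb
  if (lr_a == 0)
    return(list(ratio = NA_real_, lr_neg_a = lr_a, lr_neg_b = lr_b,
                lower = NA_real_, upper = NA_real_, se_log = NA_real_,
                scale = scale, significant = NA,
                reason = "LR- of rule A is 0: ratio undefined"))
  ratio <- lr_b / lr_a
  if (pa == 0 || pb == 0) {
    return(list(ratio = ratio, lr_neg_a = lr_a, lr_neg_b = lr_b,
                lower = NA_real_, upper = NA_real_, se_log = NA_real_,
                scale = scale, significant = NA,
                reason = "zero false-negative cell: interval undefined"))
  }
  p00 <- nd[["n00"]] / s
  q00 <- nn[["n00"]] / r
  var_log <- (1 - pa) / (s * pa) + (1 - pb) / (s * pb) -
    2 * (p00 - pa * pb) / (s * pa * pb) +
    (1 - qa) / (r * qa) + (1 - qb) / (r * qb) -
    2 * (q00 - qa * qb) / (r * qa * qb)
  var_log <- max(0, var_log)
  se <- sqrt(var_log)
  z <- qnorm(1 - (1 - level) / 2)
  if (scale == "log") {
    lo <- ratio * exp(-z * se)
    hi <- ratio * exp(z * se)
  } else {
    lo <- ratio - z * ratio * se
    hi <- ratio + z * ratio * se
  }
  list(ratio = ratio, lr_neg_a = lr_a, lr_neg_b = lr_b,
       lower = lo, upper = hi, se_log = se, scale = scale,
       significant = lo > 1 || hi < 1)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` where `po` is
#' the observed agreement proportion and `pe` the agreement expected from
#' the raters' margins. The confidence interval uses the Fleiss-Cohen-
#' Everitt large-sample standard error with a normal quantile. The table is
#' in raters orientation: `a` = both raters positive, `b` = rater 1 only,
#' `c` = rater 2 only, `d` = both negative.
#'
#' @param t A [two_by_two()] table in raters orientation with N >= 2.
#' @param level Confidence level.
#' @return List with `kappa`, `lower`, `upper`, `se`, `po`, `pe`; when both
#'   raters are constant (`pe = 1`) kappa is undefined and `NA` is returned
#'   with a `reason`.
#' @examples
#' cohen_kappa(two_by_two(40, 9, 5, 46))
#' @export
cohen_kappa <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  if (n < 2) stop("need at least 2 rated subjects")
  p <- matrix(c(t$a, t$c, t$b, t$d), 2) / n  # rows = rater 1, cols = rater 2
  prow <- rowSums(p)
  pcol <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(prow * pcol)
  if (1 - pe < 1e-12)
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                se = NA_real_, po = po, pe = pe,
                reason = "both raters constant: chance agreement is 1"))
  kappa <- (po - pe) / (1 - pe)
  term_a <- sum(diag(p) * (1 - (prow + pcol) * (1 - kappa))^2)
  off <- which(row(p) != col(p), arr.ind = TRUE)
  term_b <- (1 - kappa)^2 * sum(p[off] *
    (pcol[off[, 1]] + prow[off[, 2]])^2)
  term_c <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, term_a + term_b - term_c) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - level) / 2)
  list(kappa = kappa, lower = max(-1, kappa - z * se),
       upper = min(1, kappa + z * se), se = se, po = po, pe = pe)
}

#' Specific and overall agreement for a 2x2 agreement table
#'
#' Specific positive agreement `2a / (2a + b + c)`, specific negative
#' agreement `2d / (2d + b + c)`, and overall concordance `(a + d) / N`,
#' the latter with a Clopper-Pearson interval.
#'
#' @param t A [two_by_two()] table in raters orientation.
#' @param level Confidence level for the concordance interval.
#' @return List with `positive`, `negative`, `overall` (each `NA` with a
#'   `reason` entry when its denominator is empty), and
#'   `overall_lower` / `overall_upper`.
#' @export
specific_agreement <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  disc <- t$b + t$c
  pos <- if (2 * t$a + disc == 0) NA_real_ else 2 * t$a / (2 * t$a + disc)
  neg <- if (2 * t$d + disc == 0) NA_real_ else 2 * t$d / (2 * t$d + disc)
  ci <- proportion_ci(t$a + t$d, n, level)
  out <- list(positive = pos, negative = neg, overall = ci$estimate,
              overall_lower = ci$lower, overall_upper = ci$upper)
  if (is.na(pos)) out$reason <- "no positive classifications by either rater"
  out
}
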