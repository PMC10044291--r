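# Group-comparison statistics on 2x2 tables and logistic regression with
# AIC backward selection.

#' A 2x2 contingency table of counts
#'
#' Cells are laid out exposure-by-outcome: `a` = exposed & outcome-positive,
#' `b` = exposed & outcome-negative, `c` = unexposed & outcome-positive,
#' `d` = unexposed & outcome-negative. In the diagnostic orientation used by
#' [evaluate_rule()] the same cells read TP, FP, FN, TN.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param labels Optional character vector of length 2: exposure label and
#'   outcome label.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d, labels = c("exposure", "outcome")) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) < 1) stop("table must contain at least one count")
  structure(list(a = a, b = b, c = c, d = d, labels = labels),
            class = "two_by_two")
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(c("exposed", "unexposed"), c("pos", "neg")))
}

#' @export
print.two_by_two <- function(x, ...) {
  cat("2x2 table (", x$labels[1], " x ", x$labels[2], ")\n", sep = "")
  print(as.matrix(x))
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio `ad/bc` with the Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. For a binary exposure
#' this equals the univariate logistic-regression odds ratio. A single zero
#' cell triggers the Haldane continuity correction (0.5 added to every
#' cell), reported via the `corrected` flag; two zero cells in the same row
#' or column leave the odds ratio undefined and raise an error.
#'
#' @param t A [two_by_two()] table.
#' @param level Confidence level (default 0.95).
#' @return List with `or`, `lower`, `upper`, `corrected`.
#' @examples
#' odds_ratio(two_by_two(12, 11, 14, 70))  # fever vs radiographic pneumonia
#' @export
odds_ratio <- function(t, level = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  degenerate <- (t$a == 0 && t$b == 0) || (t$c == 0 && t$d == 0) ||
    (t$a == 0 && t$c == 0) || (t$b == 0 && t$d == 0)
  if (degenerate)
    stop("odds ratio undefined: a full row or column of the table is zero")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  list(or = unname(est), lower = unname(est * exp(-z * se)),
       upper = unname(est * exp(z * se)), corrected = corrected)
}

#' Pearson chi-squared test with Yates continuity correction
#'
#' @param t A [two_by_two()] table with no zero margin.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi2_test <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- as.matrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-squared test undefined: zero margin")
  res <- suppressWarnings(chisq.test(m, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter))
}

#' Fisher's exact test (two-sided)
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities of
#' all tables with the observed margins that are no more probable than the
#' observed one. A zero margin admits a single table, so p = 1.
#'
#' @param t A [two_by_two()] table.
#' @return List with `p_value`.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  list(p_value = fisher.test(as.matrix(t))$p.value)
}

#' Choose and run the appropriate group-comparison test
#'
#' Uses Fisher's exact test when any expected cell count is below 5, the
#' Yates-corrected chi-squared test otherwise — the conventional trigger.
#'
#' @param t A [two_by_two()] table.
#' @return List with `p_value`, `test` ("chi-squared" or "fisher"), and the
#'   minimum expected cell count.
#' @export
group_test <- function(t) {
  m <- as.matrix(t)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (min(expected) < 5) {
    list(p_value = fisher_exact(t)$p_value, test = "fisher",
         min_expected = min(expected))
  } else {
    list(p_value = chi2_test(t)$p_value, test = "chi-squared",
         min_expected = min(expected))
  }
}

#' Fit a logistic regression model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]), returning coefficients, Wald standard
#' errors and p-values, odds ratios with Wald confidence intervals, the log
#' likelihood and the AIC. Degenerate inputs — a constant outcome, a
#' constant predictor, non-convergence, or (quasi-)complete separation —
#' raise an error carrying diagnostics rather than returning a silently
#' unstable fit.
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Data.frame or matrix of predictors (binary or numeric).
#' @param level Confidence level for the odds-ratio intervals.
#' @return A `logistic_fit` object: `terms`, `coef`, `se`, `or`, `or_lower`,
#'   `or_upper`, `p_value`, `loglik`, `aic`, `n`.
#' @export
fit_logistic <- function(y, x, level = 0.95) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  keep <- stats::complete.cases(x) & !is.na(y)
  y <- y[keep]
  x <- x[keep, , drop = FALSE]
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2)
    stop("no maximum-likelihood estimate: outcome is constant (all ",
         y[1], ")")
  constant <- vapply(x, function(v) length(unique(v)) < 2, logical(1))
  if (any(constant))
    stop("constant predictor(s): ", paste(names(x)[constant], collapse = ", "))
  if (length(y) <= ncol(x) + 1)
    stop("fewer observations than parameters")
  dat <- cbind(.y = y, x)
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  probs <- fitted(fit)
  separated <- any(probs < 1e-8 | probs > 1 - 1e-8)
  if (!fit$converged || separated)
    stop("logistic fit failed: ",
         if (!fit$converged) "IRLS did not converge" else
           "perfect or quasi-complete separation detected",
         " (max |coef| = ", round(max(abs(coef(fit))), 2), ")")
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    terms = names(est),
    coef = est,
    se = se,
    or = exp(est),
    or_lower = exp(est - z * se),
    or_upper = exp(est + z * se),
    p_value = 2 * pnorm(-abs(est / se)),
    loglik = as.numeric(logLik(fit)),
    aic = fit$aic,
    n = length(y),
    glm = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, AIC = %.2f)\n", x$n, x$aic))
  df <- data.frame(term = x$terms, coef = round(x$coef, 4),
                   OR = round(x$or, 2),
                   `95% CI` = sprintf("[%.2g, %.2g]", x$or_lower, x$or_upper),
                   p = signif(x$p_value, 2), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Backward model selection minimizing the AIC
#'
#' Starting from the model containing all candidate predictors, repeatedly
#' refits every single-term deletion; if the best deletion lowers the AIC
#' below the current model's, that term is dropped, otherwise selection
#' stops. Ties within `1e-12` are broken by dropping the term that appears
#' earliest in the column order of `x` (the canonical ordering). Candidates
#' whose refit fails are skipped and recorded in the trace.
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Data.frame of candidate predictors; the initial model contains
#'   all of them.
#' @param level Confidence level passed to [fit_logistic()].
#' @return List with `fit` (the selected `logistic_fit`), `selected` (the
#'   retained predictor names), and `trace` (a data.frame with one row per
#'   candidate deletion evaluated: step, dropped term, AIC, whether taken).
#' @export
backward_select_aic <- function(y, x, level = 0.95) {
  x <- as.data.frame(x)
  current <- names(x)
  fit <- fit_logistic(y, x[, current, drop = FALSE], level = level)
  trace <- data.frame(step = 0L, drop = "<none>", aic = fit$aic,
                      taken = TRUE, stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 1L) {
    step <- step + 1L
    cand_aic <- rep(NA_real_, length(current))
    for (i in seq_along(current)) {
      reduced <- setdiff(current, current[i])
      cand <- tryCatch(
        fit_logistic(y, x[, reduced, drop = FALSE], level = level),
        error = function(e) NULL)
      cand_aic[i] <- if (is.null(cand)) NA_real_ else cand$aic
    }
    trace <- rbind(trace, data.frame(step = step, drop = current,
                                     aic = cand_aic, taken = FALSE,
                                     stringsAsFactors = FALSE))
    if (all(is.na(cand_aic))) break
    best <- min(cand_aic, na.rm = TRUE)
    if (best >= fit$aic) break
    # canonical tie-break: among candidates within 1e-12 of the best AIC,
    # drop the term earliest in the column order of x
    tied <- which(!is.na(cand_aic) & cand_aic <= best + 1e-12)
    drop_i <- tied[which.min(match(current[tied], names(x)))]
    trace$taken[nrow(trace) - length(current) + drop_i] <- TRUE
    current <- setdiff(current, current[drop_i])
    fit <- fit_logistic(y, x[, current, drop = FALSE], level = level)
  }
  list(fit = fit, selected = current, trace = trace)
}
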