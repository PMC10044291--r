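# Clinical decision rules: Boolean ANY/ALL combinations of binary signs,
# evaluated against a cohort to give the diagnostic 2x2 and the
# prevented-test / missed-case accounting.
#
# Rules serialize to a flat text form, e.g. `any(fever_temp, hypoxemia)`,
# parsed by a small recursive-descent parser; leaves are sign names.

#' Parse a rule expression
#'
#' Grammar: `expr := sign | ("any" | "all") "(" expr {"," expr} ")"`. `any`
#' is Boolean OR, `all` is Boolean AND. Leaves must be names known to
#' [sign_names()] unless `known` overrides the vocabulary.
#'
#' @param text Rule expression, e.g. `"any(fever_temp, hypoxemia)"`.
#' @param known Character vector of permissible leaf names.
#' @return An expression tree (nested list) suitable for [decision_rule()].
#' @export
parse_rule <- function(text, known = sign_names()) {
  tokens <- regmatches(text, gregexpr("[A-Za-z_][A-Za-z0-9_]*|[(),]", text))[[1]]
  if (sum(nchar(tokens)) != nchar(gsub("[[:space:]]", "", text)))
    stop("cannot tokenize rule expression: ", text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else ""
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  expect <- function(tok) {
    got <- advance()
    if (!identical(got, tok))
      stop("expected '", tok, "' but found '", got, "' in rule: ", text)
  }
  parse_expr <- function() {
    tok <- advance()
    if (tok %in% c("any", "all") && identical(peek(), "(")) {
      expect("(")
      args <- list(parse_expr())
      while (identical(peek(), ",")) {
        advance()
        args[[length(args) + 1L]] <- parse_expr()
      }
      expect(")")
      list(op = tok, args = args)
    } else {
      if (!tok %in% known)
        stop("rule references unknown sign '", tok, "'")
      tok
    }
  }
  tree <- parse_expr()
  if (pos <= length(tokens))
    stop("trailing input '", peek(), "' in rule: ", text)
  tree
}

#' Construct a named decision rule
#'
#' @param name Human-readable rule name.
#' @param expr Rule expression: either the flat text form (parsed with
#'   [parse_rule()]) or an already-built expression tree.
#' @param known Permissible leaf names (defaults to [sign_names()]).
#' @return A `decision_rule` object.
#' @examples
#' decision_rule("fever or hypoxemia", "any(fever_temp, hypoxemia)")
#' @export
decision_rule <- function(name, expr, known = sign_names()) {
  tree <- if (is.character(expr) && length(expr) == 1L)
    parse_rule(expr, known) else expr
  structure(list(name = name, tree = tree), class = "decision_rule")
}

format_tree <- function(tree) {
  if (is.character(tree)) return(tree)
  paste0(tree$op, "(", paste(vapply(tree$args, format_tree, character(1)),
                             collapse = ", "), ")")
}

#' @export
format.decision_rule <- function(x, ...) format_tree(x$tree)

#' @export
print.decision_rule <- function(x, ...) {
  cat("<decision_rule> ", x$name, ": ", format(x), "\n", sep = "")
  invisible(x)
}

rule_leaves <- function(tree) {
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, rule_leaves)))
}

eval_tree <- function(tree, signs) {
  if (is.character(tree)) return(signs[[tree]])
  vals <- lapply(tree$args, eval_tree, signs = signs)
  m <- do.call(cbind, vals)
  if (tree$op == "any") as.numeric(rowSums(m) > 0) else
    as.numeric(rowSums(m) == ncol(m))
}

#' The built-in rule registry
#'
#' The six rules evaluated against the radiographic reference standard:
#' fever AND hypoxemia, hypoxemia alone, fever alone, fever OR hypoxemia
#' (the two-vital-sign rule), the Marchello et al. meta-analysis rule
#' (any of tachycardia, tachypnea, fever, or abnormal lung auscultation),
#' and the Marchello rule extended with hypoxemia.
#'
#' @return Named list of six [decision_rule()] objects.
#' @export
builtin_rules <- function() {
  marchello <- "any(tachycardia, tachypnea, fever_temp, abnormal_auscultation)"
  specs <- list(
    fever_and_hypoxemia = c("Temperature >= 37.8 C AND oxygen saturation < 95%",
                            "all(fever_temp, hypoxemia)"),
    hypoxemia = c("Oxygen saturation < 95%", "hypoxemia"),
    fever = c("Temperature >= 37.8 C", "fever_temp"),
    fever_or_hypoxemia = c("Temperature >= 37.8 C OR oxygen saturation < 95%",
                           "any(fever_temp, hypoxemia)"),
    marchello = c("Clinical rule by Marchello et al.", marchello),
    marchello_or_hypoxemia = c(
      "Clinical rule by Marchello et al. OR oxygen saturation < 95%",
      "any(tachycardia, tachypnea, fever_temp, abnormal_auscultation, hypoxemia)")
  )
  lapply(specs, function(s) decision_rule(s[1], s[2]))
}

#' Evaluate a decision rule against a cohort
#'
#' Classifies every patient by the rule and cross-tabulates against the
#' chest X-ray reference standard. The contingency table is in diagnostic
#' orientation (a = TP, b = FP, c = FN, d = TN). `prevented_tests` counts
#' rule-negative patients — those in whom the rule would have avoided an
#' X-ray — and `missed_cases` the rule-negative patients with radiographic
#' pneumonia (the false negatives).
#'
#' @param rule A [decision_rule()], or the name of a built-in rule, or a
#'   rule expression string.
#' @param cohort A cohort data.frame (raw fields; signs are derived), or a
#'   pre-computed sign data.frame from [dichotomize()] containing
#'   `cxr_positive`.
#' @param cutoffs Cut-offs used when `cohort` holds raw fields.
#' @return A `rule_evaluation` object: `rule`, `table` (a [two_by_two()]),
#'   `n`, `n_rule_positive`, `prevented_tests`, `missed_cases`.
#' @examples
#' coh <- generate_cohort(synthetic_config(seed = 3))
#' evaluate_rule("fever_or_hypoxemia", coh)
#' @export
evaluate_rule <- function(rule, cohort, cutoffs = default_cutoffs()) {
  if (is.character(rule) && length(rule) == 1L) {
    registry <- builtin_rules()
    rule <- if (rule %in% names(registry)) registry[[rule]] else
      decision_rule(rule, rule)
  }
  stopifnot(inherits(rule, "decision_rule"))
  signs <- if (all(rule_leaves(rule$tree) %in% names(cohort)) &&
               "cxr_positive" %in% names(cohort) &&
               !"temperature" %in% names(cohort))
    cohort else dichotomize(cohort, cutoffs)
  if (!"cxr_positive" %in% names(signs))
    stop("cohort lacks the cxr_positive reference outcome")
  leaves <- rule_leaves(rule$tree)
  unknown <- setdiff(leaves, names(signs))
  if (length(unknown) > 0L)
    stop("rule references unknown sign(s): ", paste(unknown, collapse = ", "))
  used <- signs[, c(leaves, "cxr_positive"), drop = FALSE]
  incomplete <- rowSums(is.na(used)) > 0
  if (any(incomplete))
    stop("cohort is not complete-case for rule '", rule$name,
         "'; missing values for patient_id: ",
         paste(utils::head(signs$patient_id[incomplete], 5), collapse = ", "),
         if (sum(incomplete) > 5) sprintf(" (and %d more)", sum(incomplete) - 5))
  pos <- eval_tree(rule$tree, signs)
  d <- signs$cxr_positive
  tab <- two_by_two(sum(pos == 1 & d == 1), sum(pos == 1 & d == 0),
                    sum(pos == 0 & d == 1), sum(pos == 0 & d == 0),
                    labels = c(rule$name, "CXR+"))
  structure(list(rule = rule, table = tab, n = length(d),
                 n_rule_positive = sum(pos == 1),
                 prevented_tests = sum(pos == 0),
                 missed_cases = tab$c),
            class = "rule_evaluation")
}

#' Build a rule evaluation directly from 2x2 counts
#'
#' Convenience constructor for when the contingency table is known (e.g.
#' published counts) but patient-level data are not.
#'
#' @param tp,fp,fn,tn Cell counts in diagnostic orientation.
#' @param name Rule name for labeling.
#' @return A `rule_evaluation` object.
#' @export
rule_evaluation_from_counts <- function(tp, fp, fn, tn, name = "rule") {
  tab <- two_by_two(tp, fp, fn, tn, labels = c(name, "CXR+"))
  structure(list(rule = decision_rule(name, "fever_temp"), table = tab,
                 n = tp + fp + fn + tn, n_rule_positive = tp + fp,
                 prevented_tests = fn + tn, missed_cases = fn),
            class = "rule_evaluation")
}

#' @export
print.rule_evaluation <- function(x, ...) {
  cat("<rule_evaluation> ", x$rule$name, "\n", sep = "")
  print(x$table)
  cat(sprintf("rule-positive %d/%d; prevented tests %d; missed cases %d/%d\n",
              x$n_rule_positive, x$n, x$prevented_tests, x$missed_cases,
              x$table$a + x$table$c))
  invisible(x)
}
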