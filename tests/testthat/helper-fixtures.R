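# Shared fixtures: the study's 2x2 count tables (exposure x radiographic
# outcome, reconstructed from the published group counts: 26 CXR+ and 81
# CXR- patients), plus small generators used across test files.

# exposure-by-outcome tables: a = sign present & CXR+, b = sign present &
# CXR-, c = sign absent & CXR+, d = sign absent & CXR-
tab_fever <- function() two_by_two(12, 11, 14, 70)
tab_hypoxemia <- function() two_by_two(12, 17, 14, 64)
tab_tachycardia <- function() two_by_two(6, 11, 20, 70)
tab_tachypnea <- function() two_by_two(6, 19, 20, 62)
tab_auscultation <- function() two_by_two(20, 55, 6, 26)
tab_asthma <- function() two_by_two(0, 19, 26, 62)

# rule evaluations in diagnostic orientation (TP, FP, FN, TN)
ev_two_sign <- function() rule_evaluation_from_counts(18, 25, 8, 56,
                                                      "fever or hypoxemia")
ev_marchello <- function() rule_evaluation_from_counts(24, 64, 2, 17,
                                                       "four-sign rule")
ev_marchello_spo2 <- function() rule_evaluation_from_counts(25, 66, 1, 15,
                                                            "four-sign + SpO2")

# paired classifications consistent with the marginal 2x2s above (the CI
# depends on the pairing; the point estimates do not)
pc_two_sign_vs_marchello <- function()
  paired_counts(diseased = c(17, 1, 7, 1), nondiseased = c(25, 0, 39, 17),
                rule_a = "fever or hypoxemia", rule_b = "four-sign rule")
pc_marchello_vs_extended <- function()
  paired_counts(diseased = c(24, 0, 1, 1), nondiseased = c(64, 0, 2, 15),
                rule_a = "four-sign rule", rule_b = "four-sign + SpO2")

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins and sum hypergeometric probabilities <= the observed table's
fisher_enum <- function(t) {
  m <- t$a + t$b   # exposed margin
  n <- t$c + t$d
  k <- t$a + t$c   # outcome-positive margin
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  pobs <- stats::dhyper(t$a, m, n, k)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# random 2x2 with total at most `max_n` and no empty table
random_table <- function(max_n = 40) {
  repeat {
    cells <- stats::rmultinom(1, sample(4:max_n, 1), rep(0.25, 4))[, 1]
    if (sum(cells) >= 1) return(two_by_two(cells[1], cells[2],
                                           cells[3], cells[4]))
  }
}

# minimal raw cohort with exact sign patterns: each row of `grid` gives
# (fever, hypoxemia, tachycardia, tachypnea, auscultation, outcome, count)
cohort_from_patterns <- function(grid) {
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    grid[rep(i, grid$count[i]), , drop = FALSE]))
  n <- nrow(rows)
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    temperature = ifelse(rows$fever == 1, 38.5, 37.0),
    spo2 = ifelse(rows$hypoxemia == 1, 92, 98),
    heart_rate = ifelse(rows$tachycardia == 1, 110, 80),
    respiratory_rate = ifelse(rows$tachypnea == 1, 26, 16),
    sbp = 120, dbp = 80, age_years = 50,
    abnormal_auscultation = rows$auscultation,
    cxr_positive = rows$outcome,
    stringsAsFactors = FALSE)
}

pattern_grid <- function(...) {
  g <- as.data.frame(rbind(...))
  names(g) <- c("fever", "hypoxemia", "tachycardia", "tachypnea",
                "auscultation", "outcome", "count")
  g
}
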