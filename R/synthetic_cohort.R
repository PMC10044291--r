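# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: latent disease status at a fixed prevalence, binary signs drawn
# conditionally on status (independently, or coupled through a Gaussian
# copula), and raw vitals back-filled consistently with each binary sign.

# Conditional sign positivity P(sign = 1 | CXR+) and P(sign = 1 | CXR-)
# defaults: proportions among 26 CXR+ and 81 CXR- primary-care patients
# with suspected pneumonia.
default_sign_probs <- function() {
  list(
    p_pos = c(fever_temp = 12 / 26, hypoxemia = 12 / 26,
              tachycardia = 6 / 26, tachypnea = 6 / 26,
              hypotension = 0 / 26, abnormal_auscultation = 20 / 26,
              age65 = 14 / 26, sex_female = 11 / 26,
              history_of_fever = 23 / 26, sputum = 14 / 26,
              dyspnea = 13 / 26, chest_pain = 8 / 26,
              asthma = 0 / 26, copd = 3 / 26, smoker = 5 / 26,
              other_comorbidity = 2 / 26),
    p_neg = c(fever_temp = 11 / 81, hypoxemia = 17 / 81,
              tachycardia = 11 / 81, tachypnea = 19 / 81,
              hypotension = 8 / 81, abnormal_auscultation = 55 / 81,
              age65 = 20 / 81, sex_female = 54 / 81,
              history_of_fever = 51 / 81, sputum = 60 / 81,
              dyspnea = 60 / 81, chest_pain = 38 / 81,
              asthma = 19 / 81, copd = 5 / 81, smoker = 19 / 81,
              other_comorbidity = 3 / 81)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the study conditions of a primary-care cohort of 107
#' patients with clinically suspected pneumonia, of whom 24% (26/107) have
#' pneumonia visible on chest X-ray, with per-sign conditional positivity
#' probabilities matching the observed group proportions (e.g. fever in
#' 12/26 diseased vs 11/81 non-diseased patients).
#'
#' @param n_patients Cohort size (>= 1).
#' @param prevalence Probability that a patient is CXR+ (in \[0, 1\]).
#' @param p_pos,p_neg Named vectors of conditional positivity probabilities
#'   `P(sign = 1 | CXR+)` and `P(sign = 1 | CXR-)`. Both must share the same
#'   names; partial overrides of the defaults are allowed.
#' @param rho Pairwise latent correlation in \[0, 1): signs are drawn
#'   through a Gaussian copula with an equicorrelated (single shared factor)
#'   latent; `rho = 0` gives conditional independence given disease status.
#' @param missing_rate Per-raw-field probability that a measured value is
#'   missing (applied to the continuous vitals and auscultation).
#' @param seed Integer seed; the same seed yields a byte-identical cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 107, prevalence = 26 / 107,
                             p_pos = NULL, p_neg = NULL, rho = 0,
                             missing_rate = 0, seed = 1L) {
  defaults <- default_sign_probs()
  pp <- defaults$p_pos
  pn <- defaults$p_neg
  if (!is.null(p_pos)) pp[names(p_pos)] <- p_pos
  if (!is.null(p_neg)) pn[names(p_neg)] <- p_neg
  probs <- c(prevalence, pp, pn, missing_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("config error: all probabilities must lie in [0, 1]")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("config error: rho must lie in [0, 1)")
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("config error: n_patients must be >= 1")
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, p_pos = pp, p_neg = pn,
                 rho = rho, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw an n x k matrix of 0/1 signs with per-cell probabilities `p` through
# a single-factor Gaussian copula with pairwise latent correlation rho.
draw_signs <- function(p, rho) {
  n <- nrow(p)
  k <- ncol(p)
  if (rho == 0) {
    z <- matrix(rnorm(n * k), n, k)
  } else {
    w <- rnorm(n)
    z <- sqrt(rho) * matrix(w, n, k) + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  }
  (z < qnorm(p)) * 1
}

# Back-fill raw continuous vitals consistently with the binary signs:
# uniform within the abnormal or normal bin. Only the binarized values feed
# the analysis; the bins themselves are a documented modeling convenience.
backfill_raw <- function(signs, cutoffs = default_cutoffs()) {
  n <- nrow(signs)
  pick <- function(flag, lo1, hi1, lo0, hi0)
    ifelse(flag == 1, runif(n, lo1, hi1), runif(n, lo0, hi0))
  out <- data.frame(
    patient_id = signs$patient_id,
    temperature = round(pick(signs$fever_temp, cutoffs$fever_temp, 39.8,
                             36.0, cutoffs$fever_temp - 0.1), 1),
    heart_rate = round(pick(signs$tachycardia, cutoffs$tachycardia + 1, 140,
                            55, cutoffs$tachycardia)),
    respiratory_rate = round(pick(signs$tachypnea, cutoffs$tachypnea, 36,
                                  12, cutoffs$tachypnea - 1)),
    spo2 = round(pick(signs$hypoxemia, 85, cutoffs$hypoxemia - 0.1,
                      cutoffs$hypoxemia, 100), 1),
    sbp = round(pick(signs$hypotension, 80, cutoffs$hypotension_sbp,
                     cutoffs$hypotension_sbp + 10, 150)),
    dbp = round(pick(signs$hypotension, 48, cutoffs$hypotension_dbp,
                     cutoffs$hypotension_dbp + 5, 90)),
    age_years = round(pick(signs$age65, cutoffs$age65, 92,
                           18, cutoffs$age65 - 1)),
    confusion = 0,
    stringsAsFactors = FALSE
  )
  ternary <- setdiff(names(signs),
                     c("patient_id", "fever_temp", "hypoxemia", "tachycardia",
                       "tachypnea", "hypotension", "age65"))
  cbind(out, signs[, ternary, drop = FALSE])
}

#' Generate a synthetic cohort
#'
#' Disease status is Bernoulli at the configured prevalence; given status,
#' binary signs are drawn conditionally independent (or coupled through the
#' Gaussian copula when `rho > 0`); raw vitals are back-filled uniformly
#' within the bin implied by each binary sign (e.g. a hypoxemic patient gets
#' an SpO2 in \[85, 94.9\], a non-hypoxemic one in \[95, 100\]). The result
#' is deterministic for a fixed seed and leaves the caller's RNG state
#' untouched.
#'
#' @param config A [synthetic_config()].
#' @return A validated cohort data.frame of `n_patients` rows.
#' @examples
#' coh <- generate_cohort(synthetic_config(n_patients = 50, seed = 7))
#' table(coh$cxr_positive)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    disease <- rbinom(n, 1, config$prevalence)
    k <- length(config$p_pos)
    p <- matrix(rep(config$p_neg, each = n), n, k,
                dimnames = list(NULL, names(config$p_pos)))
    p[disease == 1, ] <- rep(config$p_pos, each = sum(disease))
    signs <- as.data.frame(draw_signs(p, config$rho))
    signs <- cbind(patient_id = sprintf("S%04d", seq_len(n)), signs,
                   stringsAsFactors = FALSE)
    cohort <- backfill_raw(signs)
    cohort$cxr_positive <- disease
    if (config$missing_rate > 0) {
      for (colnm in c("temperature", "heart_rate", "respiratory_rate",
                      "spo2", "sbp", "dbp", "abnormal_auscultation")) {
        drop <- runif(n) < config$missing_rate
        cohort[[colnm]][drop] <- NA
      }
    }
    validate_cohort(cohort)
  })
}

#' Cohort drawn from a known logistic model, for parameter recovery
#'
#' Generates binary signs at fixed marginal frequencies, then draws the
#' chest X-ray outcome from a logistic model
#' `logit P(CXR+ | signs) = beta0 + sum(beta_k * sign_k)`. The returned
#' truth allows recovery tests of the model-fitting code: the fitted odds
#' ratios should converge on `exp(beta)` as `n` grows.
#'
#' @param n Number of patients.
#' @param beta0 True intercept (log-odds).
#' @param beta Named vector of true log odds ratios; names must be sign
#'   names known to [dichotomize()].
#' @param marginal_p Named vector of marginal sign frequencies; defaults to
#'   the observed whole-cohort frequencies for the five analysis signs.
#' @param seed Integer seed.
#' @return A list with `cohort` (a cohort data.frame) and `truth` (the named
#'   true coefficient vector including `(Intercept)`).
#' @export
logistic_recovery_fixture <- function(n, beta0, beta,
                                      marginal_p = c(
                                        abnormal_auscultation = 75 / 107,
                                        fever_temp = 23 / 107,
                                        hypoxemia = 29 / 107,
                                        tachycardia = 17 / 107,
                                        tachypnea = 25 / 107),
                                      seed = 1L) {
  stopifnot(is.numeric(beta), !is.null(names(beta)),
            all(names(beta) %in% names(marginal_p)))
  with_seed(seed, {
    k <- length(marginal_p)
    x <- matrix(rbinom(n * k, 1, rep(marginal_p, each = n)), n, k,
                dimnames = list(NULL, names(marginal_p)))
    eta <- beta0 + as.vector(x[, names(beta), drop = FALSE] %*% beta)
    y <- rbinom(n, 1, plogis(eta))
    signs <- as.data.frame(x)
    for (nm in c("hypotension", "age65"))
      if (!nm %in% names(signs)) signs[[nm]] <- 0
    signs <- cbind(patient_id = sprintf("R%05d", seq_len(n)), signs,
                   stringsAsFactors = FALSE)
    cohort <- backfill_raw(signs)
    cohort$cxr_positive <- y
    truth <- c("(Intercept)" = beta0, beta)
    list(cohort = validate_cohort(cohort), truth = truth)
  })
}
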