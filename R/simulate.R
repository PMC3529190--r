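# ---------------------------------------------------------------------------
# Synthetic screening-cohort simulator.
#
# Risk factors are drawn from the published prevalence of the Singapore
# screening population (nested case-control totals for the factor
# marginals; the age-at-first-birth x affected-relatives cells are drawn
# jointly because their joint distribution is published).  Outcomes are
# drawn from exactly the piecewise-exponential competing-risks model the
# projection engine evaluates, which makes the simulator both a
# Monte-Carlo oracle for the engine and a self-consistent test bed for the
# calibration machinery.  All randomness flows from one explicit seed.
# ---------------------------------------------------------------------------

#' Prevalence configuration for the cohort simulator
#'
#' Defaults reproduce the Singapore screening population: category
#' prevalences of age-at-menarche, BMI and parity; the joint
#' age-at-first-birth by number-of-affected-relatives cells; the biopsy
#' fraction (1,707 of 28,883 women with at least one benign biopsy); the
#' ethnic mix in proportion 24,339 Chinese : 1,619 Malay : 1,422 Indian;
#' and entry ages in proportion 109 : 13,911 : 14,642 : 221 over the bands
#' 45-49, 50-59, 60-69 and 70-74, uniform within band.
#'
#' @param agemen Probabilities of age-at-menarche codes 0..2.
#' @param ageflb_numrel 4 x 3 matrix of joint probabilities, rows =
#'   age-at-first-birth codes 0..3, columns = relative-count codes 0..2.
#' @param bmi Probabilities of BMI codes 0..2.
#' @param parity_given Conditional split of parity >= 3 vs 1-2 among parous
#'   women (parity 0 is tied to nulliparity, see Details).
#' @param p_nulliparous Marginal probability of nulliparity (parity 0).
#' @param p_biopsy Probability of at least one benign biopsy.
#' @param ethnicity Named probabilities over `chinese`, `malay`, `indian`.
#' @param age_bands Data frame with columns `lo`, `hi`, `p` describing the
#'   entry-age mixture.
#' @param seed Optional default seed carried with the configuration.
#'
#' @details Nulliparous women necessarily sit in the "25-29 or nulliparous"
#'   age-at-first-birth cell, so nulliparity is drawn conditionally inside
#'   that cell with probability `p_nulliparous / P(cell)`; parous women
#'   split between parity >= 3 and 1-2 by `parity_given`.  This keeps both
#'   the published joint cells and the published parity marginal
#'   (65.0 / 23.7 / 11.3 per cent) exact in expectation while every record
#'   stays internally coherent.
#'
#' @return An object of class `prevalence_config`.
#' @export
prevalence_config <- function(
    agemen = c(62.19, 33.60, 4.22) / 100.01,
    ageflb_numrel = matrix(
      c(14.42, 0.43, 0.00,
        33.84, 1.10, 0.12,
        35.55, 1.71, 0.00,
        12.28, 0.49, 0.06) / 100,
      nrow = 4, byrow = TRUE),
    bmi = c(36.82, 43.06, 20.12) / 100,
    parity_given = c(65.00, 23.70) / 88.70,
    p_nulliparous = 11.30 / 100,
    p_biopsy = 1707 / 28883,
    ethnicity = c(chinese = 24339, malay = 1619, indian = 1422) /
      (24339 + 1619 + 1422),
    age_bands = data.frame(
      lo = c(45, 50, 60, 70), hi = c(49, 59, 69, 74),
      p = c(109, 13911, 14642, 221) / 28883),
    seed = NULL) {
  norm1 <- function(x) {
    if (any(x < 0)) stop("probabilities must be non-negative", call. = FALSE)
    s <- sum(x)
    if (abs(s - 1) > 1e-9)
      stop("probability vector sums to ", format(s), ", not 1", call. = FALSE)
    x / s
  }
  cfg <- list(
    agemen = norm1(agemen),
    ageflb_numrel = matrix(norm1(as.numeric(ageflb_numrel)), nrow = 4,
                           dimnames = list(ageflb = 0:3, numrel = 0:2)),
    bmi = norm1(bmi),
    parity_given = norm1(parity_given),
    p_nulliparous = p_nulliparous,
    p_biopsy = p_biopsy,
    ethnicity = norm1(ethnicity),
    age_bands = transform(age_bands, p = norm1(age_bands$p)),
    seed = seed)
  if (p_nulliparous < 0 || p_biopsy < 0 || p_nulliparous > 1 || p_biopsy > 1)
    stop("'p_nulliparous' and 'p_biopsy' must be probabilities",
         call. = FALSE)
  p_cell2 <- sum(cfg$ageflb_numrel[3, ])
  if (p_nulliparous > p_cell2 + 1e-12)
    stop("'p_nulliparous' cannot exceed the '25-29 or nulliparous' joint ",
         "cell mass (", format(p_cell2), ")", call. = FALSE)
  class(cfg) <- "prevalence_config"
  cfg
}

#' Draw raw risk-factor records
#'
#' Samples `n` women from a [prevalence_config()]: factors are independent
#' apart from the jointly drawn age-at-first-birth x relatives cell and the
#' parity/nulliparity coupling described there.  Raw values are drawn
#' uniformly within their category (entry ages uniform over whole years in
#' their band).  Atypical-hyperplasia status is left unknown, as in the
#' screening questionnaire data.
#'
#' @param n Number of women (>= 1).
#' @param config A [prevalence_config()].
#' @param seed Optional integer seed; falls back to `config$seed`.
#' @return Data frame of raw records compatible with [code_cohort()].
#' @export
sample_profiles <- function(n, config = prevalence_config(), seed = NULL) {
  stopifnot(inherits(config, "prevalence_config"))
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  samp <- function(values, prob) values[sample.int(length(prob), n,
                                                   replace = TRUE,
                                                   prob = prob)]
  # entry age: band then uniform whole year within band
  bi <- sample.int(nrow(config$age_bands), n, replace = TRUE,
                   prob = config$age_bands$p)
  entry_age <- config$age_bands$lo[bi] +
    floor(stats::runif(n) * (config$age_bands$hi[bi] -
                             config$age_bands$lo[bi] + 1))
  ethnicity <- samp(names(config$ethnicity), config$ethnicity)
  # age at menarche: representative raw years per category
  men_cat <- samp(0:2, config$agemen)
  age_menarche <- ifelse(men_cat == 0, 14 + floor(stats::runif(n) * 3),
                  ifelse(men_cat == 1, 12 + floor(stats::runif(n) * 2),
                         9 + floor(stats::runif(n) * 3)))
  # joint age-at-first-birth x relatives cell
  cell <- samp(seq_len(12), as.numeric(config$ageflb_numrel))
  flb_cat <- (cell - 1) %% 4       # column-major: rows are ageflb
  rel_cat <- (cell - 1) %/% 4
  n_relatives <- rel_cat           # >=2 represented as exactly 2
  # nulliparity only inside the 25-29-or-nulliparous cell
  p_null_in_cell <- config$p_nulliparous / sum(config$ageflb_numrel[3, ])
  nulliparous <- flb_cat == 2 & stats::runif(n) < p_null_in_cell
  age_first_birth <- ifelse(nulliparous, NA,
                     ifelse(flb_cat == 0, 16 + floor(stats::runif(n) * 4),
                     ifelse(flb_cat == 1, 20 + floor(stats::runif(n) * 5),
                     ifelse(flb_cat == 2, 25 + floor(stats::runif(n) * 5),
                            30 + floor(stats::runif(n) * 6)))))
  parity <- ifelse(nulliparous, 0L,
            ifelse(stats::runif(n) < config$parity_given[1],
                   3L + floor(stats::runif(n) * 3),
                   1L + floor(stats::runif(n) * 2)))
  bmi_cat <- samp(0:2, config$bmi)
  bmi <- ifelse(bmi_cat == 0, 18.5 + stats::runif(n) * 4.4,
         ifelse(bmi_cat == 1, 23 + stats::runif(n) * 4.4,
                27.5 + stats::runif(n) * 7.5))
  data.frame(
    id = sprintf("W%06d", seq_len(n)),
    entry_age = entry_age,
    ethnicity = ethnicity,
    age_menarche = age_menarche,
    age_first_birth = age_first_birth,
    nulliparous = nulliparous,
    n_relatives = n_relatives,
    n_biopsies = as.integer(stats::runif(n) < config$p_biopsy),
    atypical = NA,
    bmi = bmi,
    parity = as.integer(parity))
}

# Vectorized inverse-transform sampler for piecewise-constant hazards.
# delta, haz: n x J exposure and hazard matrices from entry; returns event
# times from entry (Inf when no event occurs on the table's support).
sample_piecewise <- function(delta, haz) {
  n <- nrow(delta)
  J <- ncol(delta)
  E <- stats::rexp(n)
  cumH <- matrix(0, n, J)   # cumulative hazard at interval ends
  cumT <- matrix(0, n, J)   # elapsed exposure at interval ends
  aH <- aT <- numeric(n)
  for (j in seq_len(J)) {
    aH <- aH + delta[, j] * haz[, j]
    aT <- aT + delta[, j]
    cumH[, j] <- aH
    cumT[, j] <- aT
  }
  idx <- rowSums(cumH < E) + 1L
  t_out <- rep(Inf, n)
  hit <- which(idx <= J)
  if (length(hit)) {
    at <- cbind(hit, idx[hit])
    # crossing interval necessarily has delta * haz > 0
    prevH <- cumH[at] - delta[at] * haz[at]
    t_out[hit] <- cumT[at] - delta[at] + (E[hit] - prevH) / haz[at]
  }
  t_out
}

#' Simulate competing-risk outcomes for a cohort
#'
#' For each woman a latent breast-cancer time and an independent latent
#' other-cause death time are drawn from the piecewise-exponential model
#' with hazards `B_j (1 - AR) r_ij / 1e5` and `c_j / 1e5` (relative risk
#' and AR switching at age 50), by inverse transform on the piecewise
#' cumulative hazard.  A woman is a case over the horizon when her cancer
#' time precedes both her death time and the horizon.
#'
#' @param profiles Raw or coded cohort data frame.
#' @param coeffs A [coefficient_set()].
#' @param rates Rates specification as in [predict_cohort()].
#' @param horizon Follow-up horizon in years; entry age + horizon may not
#'   exceed the rate-table support (age 90).
#' @param seed Optional integer seed.
#' @return The cohort with latent times `t_breast_cancer`, `t_other_death`
#'   (years from entry, `Inf` if the event never occurs on the support) and
#'   `case_status` appended.
#' @export
simulate_outcomes <- function(profiles, coeffs, rates = "sg-ethnic",
                              horizon = 5, seed = NULL) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(attr(profiles, "coded_model")))
    profiles <- code_cohort(profiles, model = coeffs$model)
  a <- profiles$entry_age
  if (any(a + horizon > 90))
    stop("horizon extends beyond the rate-table support (age 90)",
         call. = FALSE)
  n <- nrow(profiles)
  J <- length(.tau)
  rs <- resolve_rates(rates, profiles$ethnicity)
  older <- .age_lo >= 50
  r0 <- relative_risk(profiles, coeffs, agecat = 0)
  r1 <- relative_risk(profiles, coeffs, agecat = 1)
  Rmat <- outer(r0, rep(1, J))
  Rmat[, older] <- r1
  ar_j <- ifelse(older, coeffs$ar["plus50"], coeffs$ar["under50"])
  hb <- rs$B * rep(1 - ar_j, each = n) * Rmat / 1e5
  hc <- rs$C / 1e5
  # exposure from entry age out to the end of the table support
  delta <- exposure_matrix(a, pmax(0, max(.tau) - a), .tau)
  t_bc <- sample_piecewise(delta, hb)
  t_death <- sample_piecewise(delta, hc)
  profiles$t_breast_cancer <- t_bc
  profiles$t_other_death <- t_death
  profiles$case_status <- as.integer(t_bc < pmin(t_death, horizon))
  profiles
}

#' Simulate a full synthetic cohort
#'
#' [sample_profiles()] followed by [simulate_outcomes()] under a single
#' seed.
#'
#' @inheritParams sample_profiles
#' @inheritParams simulate_outcomes
#' @return A cohort data frame with risk factors, latent event times and
#'   `case_status`.
#' @examples
#' coh <- simulate_cohort(500, seed = 1)
#' mean(coh$case_status)
#' @export
simulate_cohort <- function(n, config = prevalence_config(),
                            coeffs = builtin_coefficients("s-gail-sbsp"),
                            rates = "sg-ethnic", horizon = 5, seed = NULL) {
  if (!is.null(seed %||% config$seed)) set.seed(seed %||% config$seed)
  profiles <- sample_profiles(n, config, seed = NULL)
  simulate_outcomes(profiles, coeffs, rates, horizon = horizon, seed = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
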