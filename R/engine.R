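# ---------------------------------------------------------------------------
# Absolute-risk projection engine.
#
# The hazard model: within age interval j a woman of relative risk r is
# subject to a constant cause-specific breast-cancer hazard
#     b_j r = B_j (1 - AR) r / 100,000        (per year)
# and an independent constant other-cause mortality hazard c_j / 100,000.
# AR and r both switch with the binary current-age category at the age-50
# interval boundary.  The probability of a first breast-cancer diagnosis in
# [a, a + h) is the sum over the intervals overlapping the horizon of
#     (b_j r / (b_j r + c_j)) * S(s_j) * (1 - exp(-delta_j (b_j r + c_j)))
# where S is the joint event-free survival from a to the start s_j of the
# overlap and delta_j the overlap length.  With delta_j = 5 and a on an
# interval boundary this is the classical 5-year Gail projection; arbitrary
# entry ages and horizons use partial exposures.
# ---------------------------------------------------------------------------

#' Relative risk of a coded profile
#'
#' Evaluates `exp(sum_k beta_k x_k + sum beta_km x_k x_m)` over a model's
#' main effects and interaction terms, where `x_k` are the profile's
#' integer category codes.  A factor whose status is unknown (`NA` code,
#' e.g. atypical hyperplasia in the Singapore data) contributes 0.  The
#' current-age category enters both as a main effect (where the model has
#' one) and through interactions.
#'
#' @param profile A `risk_profile` (see [make_profile()]) or a coded cohort
#'   data frame (see [code_cohort()]); vectorized over rows.
#' @param coeffs A [coefficient_set()].
#' @param agecat Override of the binary current-age category (0 below 50,
#'   1 at 50+).  Defaults to the profile's own `agecat`.  The projection
#'   engine evaluates both settings because a horizon can cross age 50.
#' @return Numeric vector of relative risks (1 for the referent profile).
#' @examples
#' p <- make_profile(list(entry_age = 45, n_relatives = 2))
#' relative_risk(p, builtin_coefficients("s-gail-sbsp"))  # exp(2 * 0.777)
#' @export
relative_risk <- function(profile, coeffs, agecat = NULL) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  prof <- if (inherits(profile, "risk_profile")) {
    as.data.frame(profile[!vapply(profile, is.null, TRUE)],
                  stringsAsFactors = FALSE)
  } else profile
  stopifnot(is.data.frame(prof))
  if ("nbiops" %in% names(coeffs$betas)) {
    pm <- if (inherits(profile, "risk_profile")) profile$model
          else attr(profile, "coded_model")
    if (!is.null(pm) && !identical(pm == "bcddp", coeffs$model == "bcddp"))
      stop("profile biopsy coding ('", pm, "') is incompatible with model '",
           coeffs$model, "'; recode the cohort for this model",
           call. = FALSE)
  }
  code_of <- function(f) {
    if (f == "agecat" && !is.null(agecat))
      return(rep_len(as.numeric(agecat), nrow(prof)))
    col <- f
    # coded cohorts keep raw bmi/parity alongside their codes
    if (f %in% c("bmi", "parity") && !is.null(prof[[paste0(f, "_code")]]))
      col <- paste0(f, "_code")
    x <- prof[[col]]
    if (is.null(x))
      stop("model '", coeffs$model, "' needs factor '", f,
           "' which the profile does not code", call. = FALSE)
    x <- as.numeric(x)
    mc <- coeffs$max_code[f]
    if (!is.na(mc) && any(!is.na(x) & (x < 0 | x > mc)))
      stop("code for '", f, "' outside 0..", mc, call. = FALSE)
    ifelse(is.na(x), 0, x)  # unknown contributes nothing
  }
  lp <- 0
  for (f in names(coeffs$betas)) lp <- lp + coeffs$betas[[f]] * code_of(f)
  if (nrow(coeffs$interactions))
    for (i in seq_len(nrow(coeffs$interactions)))
      lp <- lp + coeffs$interactions$beta[i] *
        code_of(coeffs$interactions$factor1[i]) *
        code_of(coeffs$interactions$factor2[i])
  exp(lp)
}

#' Baseline breast-cancer hazard of an age interval
#'
#' The composite incidence `B_j` is deflated by the attributable-risk
#' fraction of the age category interval `j` falls in, and rescaled from
#' per-100,000 to a per-year hazard: `B_j (1 - AR) / 100000`.
#'
#' @param rates A [rate_table()].
#' @param coeffs A [coefficient_set()] (supplies the AR pair).
#' @param j Interval index.
#' @param agecat Age category of the interval; defaults to 1 when the
#'   interval starts at or above age 50.
#' @return Per-year baseline hazard.
#' @export
baseline_hazard <- function(rates, coeffs, j, agecat = NULL) {
  stopifnot(inherits(rates, "rate_table"), inherits(coeffs, "coefficient_set"))
  if (any(j < 1 | j > nrow(rates$intervals)))
    stop("interval index out of range", call. = FALSE)
  if (is.null(agecat)) agecat <- as.integer(rates$intervals$age_lo[j] >= 50)
  ar <- ifelse(agecat >= 1, coeffs$ar["plus50"], coeffs$ar["under50"])
  rates$intervals$incidence[j] * (1 - ar) / 1e5
}

# Vectorized projection core.  delta, hb, hc are n x J matrices of
# per-interval exposures (years) and per-year cause-specific hazards.
# Returns the three-way decomposition; the columns telescope so the three
# probabilities sum to 1 up to floating rounding.
project_core <- function(delta, hb, hc) {
  n <- nrow(delta)
  lam <- hb + hc
  p_bc <- numeric(n)
  p_death <- numeric(n)
  surv <- rep(1, n)
  for (j in seq_len(ncol(delta))) {
    dl <- delta[, j] * lam[, j]
    mass <- surv * (-expm1(-dl))          # P(first event in this slice)
    pos <- lam[, j] > 0
    fb <- fc <- numeric(n)
    fb[pos] <- hb[pos, j] / lam[pos, j]
    fc[pos] <- hc[pos, j] / lam[pos, j]
    p_bc <- p_bc + fb * mass
    p_death <- p_death + fc * mass
    surv <- surv * exp(-dl)
  }
  list(p_breast_cancer = p_bc, p_other_death = p_death, p_event_free = surv)
}

# Per-interval exposures of [a, a+h) against the table grid; n x J matrix.
exposure_matrix <- function(a, h, tau) {
  lo <- c(0, tau[-length(tau)])
  t(vapply(seq_along(a), function(i) {
    pmax(0, pmin(tau, a[i] + h[i]) - pmax(lo, a[i]))
  }, numeric(length(tau))))
}

#' Project absolute invasive breast-cancer risk
#'
#' Computes the probability that a woman of the given risk profile develops
#' invasive breast cancer within `h` years of age `a`, together with the
#' competing probability of dying of another cause first and the
#' probability of remaining event-free; the three sum to one.  Relative
#' risk and attributable risk both switch at the age-50 interval boundary
#' if the horizon crosses it.
#'
#' @param profile A `risk_profile`.
#' @param coeffs A [coefficient_set()].
#' @param rates A [rate_table()] or population identifier.
#' @param a Start age in years (defaults to the profile's entry age); must
#'   be at least 20.
#' @param h Horizon in years (> 0); `a + h` may not exceed 90, beyond which
#'   the rate tables end.
#' @return An object of class `risk_projection` with elements
#'   `p_breast_cancer`, `p_other_death`, `p_event_free`, `r_under50`,
#'   `r_50plus`, `a`, `h` and a per-interval `trace` data frame (interval,
#'   exposure, cause-specific per-year hazards).
#' @examples
#' p <- make_profile(list(entry_age = 50, age_menarche = 13,
#'                        age_first_birth = 26))
#' absolute_risk(p, builtin_coefficients("s-gail-sbsp"), "sg-chinese")
#' @export
absolute_risk <- function(profile, coeffs, rates, a = profile$entry_age,
                          h = 5) {
  stopifnot(inherits(profile, "risk_profile"))
  if (is.character(rates)) rates <- builtin_rate_table(rates)
  stopifnot(inherits(rates, "rate_table"))
  tau <- rates$intervals$tau
  if (!is.numeric(a) || length(a) != 1 || a < 20)
    stop("start age 'a' must be a single age of at least 20", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("horizon 'h' must be positive", call. = FALSE)
  if (a + h > max(tau) || a + h > 90)
    stop("projection beyond age ", min(max(tau), 90),
         " is outside the rate-table support", call. = FALSE)
  r0 <- relative_risk(profile, coeffs, agecat = 0)
  r1 <- relative_risk(profile, coeffs, agecat = 1)
  older <- rates$intervals$age_lo >= 50
  r_j <- ifelse(older, r1, r0)
  ar_j <- ifelse(older, coeffs$ar["plus50"], coeffs$ar["under50"])
  hb <- rates$intervals$incidence * (1 - ar_j) * r_j / 1e5
  hc <- rates$intervals$mortality / 1e5
  delta <- exposure_matrix(a, h, tau)
  res <- project_core(delta, matrix(hb, 1), matrix(hc, 1))
  on <- delta[1, ] > 0
  out <- list(
    p_breast_cancer = res$p_breast_cancer,
    p_other_death = res$p_other_death,
    p_event_free = res$p_event_free,
    r_under50 = r0, r_50plus = r1, a = a, h = h,
    trace = data.frame(
      j = which(on),
      age_lo = pmax(rates$intervals$age_lo, a)[on],
      exposure = delta[1, on],
      hazard_bc = hb[on],
      hazard_death = hc[on]))
  class(out) <- "risk_projection"
  out
}

#' Project risk for a whole cohort
#'
#' Vectorized [absolute_risk()] over a coded cohort.  Rates may be one
#' table for everyone, or the string `"sg-ethnic"` to route each woman to
#' her ethnic group's Singapore table (`chinese`, `malay`, `indian`;
#' anything else falls back to the overall Singapore table), mirroring how
#' race-specific rates are used in the Singapore calibration.
#'
#' @param cohort Raw or coded cohort data frame; raw cohorts are coded with
#'   [code_cohort()] for `coeffs$model` first.
#' @param coeffs A [coefficient_set()].
#' @param rates A [rate_table()], a population identifier, or
#'   `"sg-ethnic"`.
#' @param horizon Projection horizon in years (default 5).
#' @return The cohort with columns `r_under50`, `r_50plus`,
#'   `p_breast_cancer`, `p_other_death`, `p_event_free` appended.
#' @export
predict_cohort <- function(cohort, coeffs, rates = "sg-ethnic", horizon = 5) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (is.null(attr(cohort, "coded_model")))
    cohort <- code_cohort(cohort, model = coeffs$model)
  a <- cohort$entry_age
  if (any(a + horizon > 90))
    stop("projection beyond age 90 is outside the rate-table support",
         call. = FALSE)
  rs <- resolve_rates(rates, cohort$ethnicity)
  tau <- .tau
  older <- .age_lo >= 50
  r0 <- relative_risk(cohort, coeffs, agecat = 0)
  r1 <- relative_risk(cohort, coeffs, agecat = 1)
  n <- nrow(cohort)
  J <- length(tau)
  ar_j <- ifelse(older, coeffs$ar["plus50"], coeffs$ar["under50"])
  # n x J hazards: per-woman rates row times her relative risk per interval
  Rmat <- outer(r0, rep(1, J))
  Rmat[, older] <- r1
  hb <- rs$B * rep(1 - ar_j, each = n) * Rmat / 1e5
  hc <- rs$C / 1e5
  delta <- exposure_matrix(a, rep_len(horizon, n), tau)
  res <- project_core(delta, hb, hc)
  cohort$r_under50 <- r0
  cohort$r_50plus <- r1
  cohort$p_breast_cancer <- res$p_breast_cancer
  cohort$p_other_death <- res$p_other_death
  cohort$p_event_free <- res$p_event_free
  cohort
}

# Resolve a rates argument to n x J matrices of per-100,000 rates.
resolve_rates <- function(rates, ethnicity) {
  n <- length(ethnicity)
  if (is.character(rates) && identical(rates, "sg-ethnic")) {
    pop <- ifelse(ethnicity %in% "chinese", "sg-chinese",
           ifelse(ethnicity %in% "malay", "sg-malay",
           ifelse(ethnicity %in% "indian", "sg-indian", "sg-overall")))
    tabs <- lapply(.populations, builtin_rate_table)
    names(tabs) <- .populations
    idx <- match(pop, .populations)
    Ball <- t(vapply(tabs, function(t) t$intervals$incidence,
                     numeric(length(.tau))))
    Call <- t(vapply(tabs, function(t) t$intervals$mortality,
                     numeric(length(.tau))))
    return(list(B = Ball[idx, , drop = FALSE], C = Call[idx, , drop = FALSE]))
  }
  if (is.character(rates)) rates <- builtin_rate_table(rates)
  stopifnot(inherits(rates, "rate_table"))
  if (!identical(rates$intervals$tau, .tau))
    stop("cohort prediction requires the standard 15-interval age grid",
         call. = FALSE)
  list(B = matrix(rates$intervals$incidence, n, length(.tau), byrow = TRUE),
       C = matrix(rates$intervals$mortality, n, length(.tau), byrow = TRUE))
}

#' Relative-risk grid of a model
#'
#' Expands a coefficient set into the grid of combined relative risks over
#' its factor categories: one block per main-effect factor, a joint block
#' for age-at-first-birth by number of affected relatives (with its
#' interaction term where the model has one), and, for models with a
#' biopsy-by-age interaction, a biopsy block stratified by age category
#' whose referent is the no-biopsy woman of the same age category.
#'
#' @param coeffs A [coefficient_set()].
#' @param digits Rounding applied to the `rr` column (default 2, matching
#'   the conventional presentation); `rr_exact` is always unrounded.
#' @return Data frame with columns `factor`, `category`, `rr`, `rr_exact`.
#' @examples
#' rr_table(builtin_coefficients("s-gail-sbsp"))
#' @export
rr_table <- function(coeffs, digits = 2) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  b <- coeffs$betas
  int_beta <- function(f1, f2) {
    ii <- coeffs$interactions
    hit <- (ii$factor1 == f1 & ii$factor2 == f2) |
           (ii$factor1 == f2 & ii$factor2 == f1)
    if (any(hit)) ii$beta[hit][1] else 0
  }
  labs <- list(
    agemen = c(">=14", "12-13", "<12"),
    ageflb = c("<20", "20-24", "25-29 or nulliparous", ">=30"),
    numrel = c("0", "1", ">=2"),
    bmi = c("<23.0", "23.0-27.4", ">=27.5"),
    parity = c(">=3", "1-2", "0"))
  rows <- list()
  add <- function(factor, category, lp)
    rows[[length(rows) + 1L]] <<- data.frame(
      factor = factor, category = category, rr_exact = exp(lp))
  if ("agemen" %in% names(b))
    for (x in 0:coeffs$max_code["agemen"])
      add("agemen", labs$agemen[x + 1], x * b[["agemen"]])
  if ("nbiops" %in% names(b)) {
    bi <- int_beta("nbiops", "agecat")
    acs <- if (bi != 0) 0:1 else 0
    for (ac in acs)
      for (x in 0:coeffs$max_code["nbiops"])
        add("nbiops",
            paste0(if (bi != 0) paste0("agecat", c("<50", ">=50")[ac + 1],
                                       " & "),
                   "nbiops ", x),
            x * b[["nbiops"]] + x * ac * bi)
  }
  if (all(c("ageflb", "numrel") %in% names(b))) {
    bi <- int_beta("ageflb", "numrel")
    for (f in 0:coeffs$max_code["ageflb"])
      for (r in 0:coeffs$max_code["numrel"])
        add("ageflb x numrel",
            paste0(labs$ageflb[f + 1], " & numrel ", labs$numrel[r + 1]),
            f * b[["ageflb"]] + r * b[["numrel"]] + f * r * bi)
  }
  for (f in c("bmi", "parity"))
    if (f %in% names(b))
      for (x in 0:coeffs$max_code[f])
        add(f, labs[[f]][x + 1], x * b[[f]])
  out <- do.call(rbind, rows)
  out$rr <- round(out$rr_exact, digits)
  out[, c("factor", "category", "rr", "rr_exact")]
}

#' @export
print.risk_projection <- function(x, digits = 4, ...) {
  cat(sprintf("Absolute risk projection: age %g over %g years\n", x$a, x$h))
  cat(sprintf("  P(invasive breast cancer) = %.*g\n", digits,
              x$p_breast_cancer))
  cat(sprintf("  P(death, other causes)    = %.*g\n", digits,
              x$p_other_death))
  cat(sprintf("  P(event-free)             = %.*g\n", digits,
              x$p_event_free))
  cat(sprintf("  relative risk: %.4g (<50), %.4g (50+)\n",
              x$r_under50, x$r_50plus))
  invisible(x)
}
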