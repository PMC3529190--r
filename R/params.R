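#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Shared age grid.
#
# All built-in rate tables use 15 age intervals with upper bounds
# tau_j = 20, 25, ..., 90.  The first interval spans ages 0-19; the last
# (>= 85) is open-ended in the published tables but carries a nominal 5-year
# width here because the projection recursion needs finite exposures, so
# projections are refused beyond age 90.
# ---------------------------------------------------------------------------

.tau    <- seq(20, 90, by = 5)
.age_lo <- c(0, seq(20, 85, by = 5))
.age_hi <- c(19, seq(24, 89, by = 5))

.populations <- c("caucasian-1983-87", "sg-overall", "sg-chinese",
                  "sg-malay", "sg-indian")
.models <- c("bcddp", "gail-sbsp", "s-gail-sbsp", "e-gail-sbsp")

# Age-specific invasive breast-cancer incidence (B_j) and other-cause
# mortality (c_j), both per 100,000 woman-years.  Stored exactly as
# published; the engine divides by 100,000 at the point of use.
.rate_registry <- list(
  "caucasian-1983-87" = list(
    B = c(0, 1, 7.6, 26.6, 66.1, 126.5, 186.6, 221.1, 272.1, 334.8,
          392.3, 417.8, 443.9, 442.1, 410.9),
    c = c(0, 49.3, 53.1, 62.5, 82.5, 130.7, 218.1, 365.5, 585.2, 943.9,
          1502.8, 2383.9, 3883.2, 6682.8, 14490.8)),
  "sg-overall" = list(
    B = c(0.3, 1.9, 8.1, 24.8, 57.6, 118.7, 162.6, 187.0, 204.3, 199.1,
          193.9, 166.5, 179.0, 189.8, 166.2),
    c = c(11.7, 14.3, 14.2, 19.8, 32.6, 58.5, 106.2, 182.1, 319.1, 565.9,
          989.5, 1798.6, 3285.3, 5681.0, 11425.5)),
  "sg-chinese" = list(
    B = c(0.2, 1.8, 7.0, 25.5, 60.3, 121.5, 169.1, 193.6, 211.0, 202.1,
          199.8, 161.3, 180.9, 191.4, 164.5),
    c = c(10.5, 11.9, 12.5, 16.8, 29.4, 51.6, 95.1, 165.1, 271.1, 489.6,
          856.5, 1624.3, 3001.6, 5388.2, 11352.1)),
  "sg-malay" = list(
    B = c(0.5, 1.1, 15.9, 27.7, 60.0, 123.7, 145.1, 158.4, 167.0, 209.3,
          131.9, 199.1, 128.6, 188.4, 117.6),
    c = c(17.4, 25.7, 22.5, 47.0, 53.9, 98.6, 175.1, 297.5, 617.7, 1093.0,
          2040.3, 3034.6, 5678.6, 8681.2, 13323.5)),
  "sg-indian" = list(
    B = c(0.5, 2.2, 4.9, 5.9, 31.6, 87.9, 128.4, 147.2, 181.5, 157.6,
          219.5, 152.5, 197.2, 125.0, 375.0),
    c = c(11.0, 12.9, 19.7, 14.8, 34.8, 60.7, 111.9, 212.6, 445.9, 853.3,
          1158.5, 1932.2, 3662.0, 6093.8, 11000.0))
)

# Attributable-risk pairs: fraction of composite incidence attributable to
# the modelled factors, split by the binary current-age category at 50.
.ar_bcddp     <- c(under50 = 0.4771, plus50 = 0.4736)
.ar_singapore <- c(under50 = 0.5356, plus50 = 0.5397)

#' Construct a rate table
#'
#' A rate table couples an age grid with age-specific invasive breast-cancer
#' incidence and other-cause ("competing") mortality for one population.
#' Rates are stored per 100,000 woman-years, exactly as they are published;
#' the projection engine rescales them internally.
#'
#' @param population Identifier for the population the rates describe.
#' @param incidence Numeric vector of incidence rates per 100,000
#'   woman-years, one per interval.
#' @param mortality Numeric vector of other-cause mortality rates per
#'   100,000 woman-years, one per interval.
#' @param tau Strictly increasing upper age bounds of the intervals (years).
#'   Defaults to the standard grid 20, 25, ..., 90.
#' @return An object of class `rate_table`.
#' @seealso [builtin_rate_table()] for the shipped tables.
#' @export
rate_table <- function(population, incidence, mortality, tau = .tau) {
  stopifnot(is.character(population), length(population) == 1L)
  n <- length(tau)
  if (length(incidence) != n || length(mortality) != n)
    stop("'incidence' and 'mortality' must have one value per interval (",
         n, ")", call. = FALSE)
  if (n < 1L || any(diff(tau) <= 0))
    stop("interval bounds 'tau' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(incidence)) || any(incidence < 0))
    stop("negative or non-finite incidence rate", call. = FALSE)
  if (any(!is.finite(mortality)) || any(mortality < 0))
    stop("negative or non-finite mortality rate", call. = FALSE)
  lo <- c(0, tau[-n])
  out <- list(
    population = population,
    intervals = data.frame(
      j = seq_len(n), age_lo = lo, age_hi = tau - 1, tau = tau,
      incidence = incidence, mortality = mortality),
    width = if (n > 1L) diff(tau)[1] else tau
  )
  class(out) <- "rate_table"
  out
}

#' Built-in population rate tables
#'
#' Returns one of the five shipped rate tables: USA Caucasian women
#' (1983-1987, the GAIL baseline) or Singapore 2003-2007 rates, overall and
#' for the Chinese, Malay and Indian ethnic groups.
#'
#' @param population One of `"caucasian-1983-87"`, `"sg-overall"`,
#'   `"sg-chinese"`, `"sg-malay"`, `"sg-indian"`.
#' @return A [rate_table()].
#' @examples
#' rt <- builtin_rate_table("sg-chinese")
#' rt$intervals[7, ]  # ages 45-49
#' @export
builtin_rate_table <- function(population) {
  population <- match_id(population, .populations, "population")
  reg <- .rate_registry[[population]]
  rate_table(population, reg$B, reg$c)
}

#' List built-in identifiers
#'
#' @return Character vector of the shipped population (rate-table) or model
#'   (coefficient-set) identifiers.
#' @export
rate_populations <- function() .populations

#' @rdname rate_populations
#' @export
model_names <- function() .models

# match an identifier against valid choices with a descriptive failure
match_id <- function(x, choices, what) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop("unknown ", what, " '", paste(x, collapse = ","),
         "'; valid choices are: ", paste(choices, collapse = ", "),
         call. = FALSE)
  x
}

#' Construct a coefficient set
#'
#' A coefficient set holds one model's log relative-risk coefficients, its
#' interaction terms, the category-code ranges each factor admits, and the
#' attributable-risk (AR) pair used to deflate composite incidence to a
#' referent-profile baseline.  Factor codes are consecutive integers
#' starting at 0 (the referent).
#'
#' @param model Identifier for the model.
#' @param betas Named numeric vector of main-effect coefficients (log RR per
#'   unit category code).
#' @param interactions A data frame with columns `factor1`, `factor2`,
#'   `beta`, or `NULL` for none.
#' @param max_code Named integer vector giving the largest admissible
#'   category code of every factor the model consumes.
#' @param ar Length-2 numeric, the attributable-risk fractions
#'   `c(under50 = , plus50 = )`, each in `[0, 1)`.
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(model, betas, interactions = NULL, max_code,
                            ar = c(under50 = 0, plus50 = 0)) {
  stopifnot(is.character(model), length(model) == 1L)
  if (is.null(names(betas)) || any(!nzchar(names(betas))))
    stop("'betas' must be a fully named numeric vector", call. = FALSE)
  if (is.null(interactions))
    interactions <- data.frame(factor1 = character(), factor2 = character(),
                               beta = numeric())
  stopifnot(all(c("factor1", "factor2", "beta") %in% names(interactions)))
  known <- union(names(betas), names(max_code))
  bad <- setdiff(c(interactions$factor1, interactions$factor2), known)
  if (length(bad))
    stop("interaction references unknown factor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(names(max_code)))
    stop("'max_code' must be named", call. = FALSE)
  if (any(max_code < 0) || any(max_code != round(max_code)))
    stop("'max_code' entries must be non-negative integers", call. = FALSE)
  ar <- as.numeric(ar)
  if (length(ar) != 2L || any(!is.finite(ar)) || any(ar < 0) || any(ar >= 1))
    stop("attributable-risk fractions must lie in [0, 1)", call. = FALSE)
  names(ar) <- c("under50", "plus50")
  structure(list(model = model, betas = betas, interactions = interactions,
                 max_code = max_code, ar = ar),
            class = "coefficient_set")
}

#' Built-in model coefficient sets
#'
#' The four shipped models:
#' \describe{
#'   \item{`bcddp`}{The original Gail coefficients estimated on the Breast
#'     Cancer Detection Demonstration Project: agecat, agemen, ageflb,
#'     numrel, nbiops (codes 0/1/2), atypical hyperplasia, and the
#'     nbiops x agecat and ageflb x numrel interactions.  Atypical
#'     hyperplasia contributes to the linear predictor only when its status
#'     is known; an unknown status contributes 0.}
#'   \item{`gail-sbsp`}{The same coefficients applied with Singapore rate
#'     tables; biopsies are coded 0 / >=1 (any biopsy history counts as a
#'     single biopsy) and atypical hyperplasia is treated as unknown.}
#'   \item{`s-gail-sbsp`}{Simplified three-factor model (agemen, ageflb,
#'     numrel) re-estimated on the Singapore nested case-control study.}
#'   \item{`e-gail-sbsp`}{Extended model adding BMI and parity, with the
#'     Singapore attributable-risk pair (0.5356 / 0.5397).}
#' }
#'
#' The `bcddp`, `gail-sbsp` and `s-gail-sbsp` sets default to the BCDDP
#' attributable-risk pair (0.4771 under 50, 0.4736 at 50+).  For
#' `s-gail-sbsp` the published record does not state which pair was used,
#' so the pair is overridable through `ar`.
#'
#' @param model One of `"bcddp"`, `"gail-sbsp"`, `"s-gail-sbsp"`,
#'   `"e-gail-sbsp"`.
#' @param ar Optional length-2 override of the attributable-risk pair.
#' @return A [coefficient_set()].
#' @examples
#' builtin_coefficients("s-gail-sbsp")$betas
#' @export
builtin_coefficients <- function(model, ar = NULL) {
  model <- match_id(model, .models, "model")
  cs <- switch(model,
    "bcddp" = coefficient_set(
      model,
      betas = c(agecat = 0.01081, agemen = 0.09401, ageflb = 0.21863,
                numrel = 0.95830, nbiops = 0.52926, atypical = 0.57405),
      interactions = data.frame(
        factor1 = c("nbiops", "ageflb"),
        factor2 = c("agecat", "numrel"),
        beta    = c(-0.28804, -0.19081)),
      max_code = c(agecat = 1, agemen = 2, ageflb = 3, numrel = 2,
                   nbiops = 2, atypical = 1),
      ar = .ar_bcddp),
    "gail-sbsp" = coefficient_set(
      model,
      betas = c(agecat = 0.01081, agemen = 0.09401, ageflb = 0.21863,
                numrel = 0.95830, nbiops = 0.52926),
      interactions = data.frame(
        factor1 = c("nbiops", "ageflb"),
        factor2 = c("agecat", "numrel"),
        beta    = c(-0.28804, -0.19081)),
      max_code = c(agecat = 1, agemen = 2, ageflb = 3, numrel = 2,
                   nbiops = 1),
      ar = .ar_bcddp),
    "s-gail-sbsp" = coefficient_set(
      model,
      betas = c(agemen = 0.238, ageflb = 0.183, numrel = 0.777),
      max_code = c(agemen = 2, ageflb = 3, numrel = 2),
      ar = .ar_bcddp),
    "e-gail-sbsp" = coefficient_set(
      model,
      betas = c(agemen = 0.204, ageflb = 0.170, numrel = 0.774,
                bmi = 0.380, parity = 0.203),
      max_code = c(agemen = 2, ageflb = 3, numrel = 2, bmi = 2, parity = 2),
      ar = .ar_singapore)
  )
  if (!is.null(ar)) {
    ar <- as.numeric(ar)
    if (length(ar) != 2L || any(ar < 0) || any(ar >= 1))
      stop("'ar' override must be two fractions in [0, 1)", call. = FALSE)
    cs$ar <- c(under50 = ar[1], plus50 = ar[2])
  }
  cs
}

# ---------------------------------------------------------------------------
# Structured-text (YAML) serialization.  Files carry a versioned header so
# the schema can evolve; loading re-validates every invariant.
# ---------------------------------------------------------------------------

#' Save or load a rate table
#'
#' Rate tables are serialized to a small versioned YAML document holding the
#' population identifier and one record per age interval.  `load_rate_table`
#' re-validates every invariant (monotone bounds, non-negative rates) and
#' names the offending field on failure; `save` then `load` is the identity
#' at the printed precision.
#'
#' @param x A [rate_table()].
#' @param path File path.
#' @return `load_rate_table` returns a [rate_table()];
#'   `save_rate_table` returns `path` invisibly.
#' @export
save_rate_table <- function(x, path) {
  stopifnot(inherits(x, "rate_table"))
  doc <- list(
    format = "searisk-rate-table", version = 1L,
    population = x$population,
    intervals = lapply(seq_len(nrow(x$intervals)), function(i) {
      r <- x$intervals[i, ]
      list(j = r$j, tau = r$tau, incidence = r$incidence,
           mortality = r$mortality)
    }))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' @rdname save_rate_table
#' @export
load_rate_table <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "searisk-rate-table"))
    stop("not a searisk rate-table file (missing or wrong 'format' header): ",
         path, call. = FALSE)
  if (is.null(doc$population))
    stop("rate-table file lacks a 'population' field", call. = FALSE)
  iv <- doc$intervals
  if (!length(iv)) stop("rate-table file has no 'intervals'", call. = FALSE)
  get_num <- function(field) {
    v <- vapply(iv, function(r) {
      if (is.null(r[[field]]))
        stop("interval record missing field '", field, "'", call. = FALSE)
      as.numeric(r[[field]])
    }, numeric(1))
    v
  }
  tau <- get_num("tau")
  if (any(diff(tau) <= 0))
    stop("field 'tau': interval bounds out of order", call. = FALSE)
  B <- get_num("incidence")
  if (any(B < 0)) stop("field 'incidence': negative rate", call. = FALSE)
  cc <- get_num("mortality")
  if (any(cc < 0)) stop("field 'mortality': negative rate", call. = FALSE)
  rate_table(doc$population, B, cc, tau = tau)
}

#' Save or load a coefficient set
#'
#' @param x A [coefficient_set()].
#' @param path File path.
#' @return `load_coefficients` returns a [coefficient_set()];
#'   `save_coefficients` returns `path` invisibly.
#' @export
save_coefficients <- function(x, path) {
  stopifnot(inherits(x, "coefficient_set"))
  doc <- list(
    format = "searisk-coefficients", version = 1L,
    model = x$model,
    ar = list(under50 = unname(x$ar["under50"]),
              plus50 = unname(x$ar["plus50"])),
    betas = as.list(x$betas),
    max_code = as.list(x$max_code),
    interactions = lapply(seq_len(nrow(x$interactions)), function(i) {
      r <- x$interactions[i, ]
      list(factors = c(r$factor1, r$factor2), beta = r$beta)
    }))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' @rdname save_coefficients
#' @export
load_coefficients <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "searisk-coefficients"))
    stop("not a searisk coefficients file (missing or wrong 'format' ",
         "header): ", path, call. = FALSE)
  betas <- unlist(doc$betas)
  mc <- unlist(doc$max_code)
  ints <- if (length(doc$interactions)) {
    data.frame(
      factor1 = vapply(doc$interactions, function(r) r$factors[[1]], ""),
      factor2 = vapply(doc$interactions, function(r) r$factors[[2]], ""),
      beta = vapply(doc$interactions, function(r) as.numeric(r$beta), 0))
  } else NULL
  coefficient_set(doc$model, betas = betas, interactions = ints,
                  max_code = mc,
                  ar = c(under50 = doc$ar$under50, plus50 = doc$ar$plus50))
}

#' Export every built-in parameter table as plain CSV
#'
#' Writes `rate_tables.csv` (one row per population x interval) and
#' `coefficients.csv` (one row per model term, including interaction terms
#' and attributable-risk fractions) for side-by-side inspection against the
#' published tables.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_parameter_csv <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rates <- do.call(rbind, lapply(.populations, function(p) {
    rt <- builtin_rate_table(p)
    cbind(population = p, rt$intervals)
  }))
  fr <- file.path(dir, "rate_tables.csv")
  utils::write.csv(rates, fr, row.names = FALSE, quote = FALSE)
  coefs <- do.call(rbind, lapply(.models, function(m) {
    cs <- builtin_coefficients(m)
    rbind(
      data.frame(model = m, term = names(cs$betas), type = "main",
                 beta = unname(cs$betas)),
      if (nrow(cs$interactions))
        data.frame(model = m,
                   term = paste0(cs$interactions$factor1, "x",
                                 cs$interactions$factor2),
                   type = "interaction", beta = cs$interactions$beta),
      data.frame(model = m, term = c("ar_under50", "ar_50plus"),
                 type = "attributable-risk", beta = unname(cs$ar)))
  }))
  fc <- file.path(dir, "coefficients.csv")
  utils::write.csv(coefs, fc, row.names = FALSE, quote = FALSE)
  invisible(c(fr, fc))
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Rate table:", x$population, "\n")
  cat(nrow(x$intervals), "age intervals,",
      "rates per 100,000 woman-years\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("Coefficient set:", x$model, "\n")
  cat("Attributable risk: ", sprintf("%.4f", x$ar["under50"]), " (<50), ",
      sprintf("%.4f", x$ar["plus50"]), " (50+)\n", sep = "")
  cat("Main effects:\n")
  print(x$betas)
  if (nrow(x$interactions)) {
    cat("Interactions:\n")
    print(x$interactions, row.names = FALSE)
  }
  invisible(x)
}
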