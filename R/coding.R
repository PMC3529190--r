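# ---------------------------------------------------------------------------
# Risk-factor category coding.
#
# Each coder maps a raw questionnaire value to the integer category code the
# models consume.  Missing values (NA) never raise: an unknown maps to the
# referent bucket of its factor (code 0, except age-at-first-birth whose
# referent structure makes the "25-29 or nulliparous" bucket, code 2, the
# conventional unknown destination).  Category bounds are closed on the
# printed lower edge: BMI 23.0 is code 1, 27.5 is code 2, age 50 is the
# older age category.  All coders are vectorized.
# ---------------------------------------------------------------------------

#' Code age at menarche
#'
#' Categories: >= 14 years -> 0, 12-13 -> 1, < 12 -> 2; unknown -> 0.
#'
#' @param age_menarche Age at menarche in whole years, `NA` for unknown.
#' @return Integer codes.
#' @export
code_agemen <- function(age_menarche) {
  chk_positive(age_menarche, "age_menarche")
  out <- ifelse(is.na(age_menarche), 0L,
         ifelse(age_menarche >= 14, 0L,
         ifelse(age_menarche >= 12, 1L, 2L)))
  as.integer(out)
}

#' Code age at first live birth
#'
#' Categories: < 20 -> 0, 20-24 -> 1, 25-29 or nulliparous -> 2, >= 30 -> 3.
#' An unknown age maps by default to code 2, the bucket that already pools
#' heterogeneous histories (nulliparity) in this coding; pass
#' `unknown_code` to change that policy.
#'
#' @param age_first_birth Age in whole years at first live birth, `NA` for
#'   unknown.
#' @param nulliparous Logical, recycled; `TRUE` forces code 2 regardless of
#'   `age_first_birth`.
#' @param unknown_code Code assigned when the age is unknown and the woman
#'   is not known nulliparous (default 2).
#' @return Integer codes.
#' @export
code_ageflb <- function(age_first_birth, nulliparous = FALSE,
                        unknown_code = 2L) {
  chk_positive(age_first_birth, "age_first_birth")
  n <- max(length(age_first_birth), length(nulliparous))
  age <- rep_len(age_first_birth, n)
  np <- rep_len(isTRUE_vec(nulliparous), n)
  out <- ifelse(np, 2L,
         ifelse(is.na(age), as.integer(unknown_code),
         ifelse(age < 20, 0L,
         ifelse(age < 25, 1L,
         ifelse(age < 30, 2L, 3L)))))
  as.integer(out)
}

#' Code number of affected first-degree relatives
#'
#' Categories: 0 -> 0, 1 -> 1, >= 2 -> 2; unknown -> 0.
#'
#' @param n_relatives Count of first-degree relatives (mother, sister,
#'   daughter) with breast cancer, `NA` for unknown.
#' @return Integer codes.
#' @export
code_numrel <- function(n_relatives) {
  chk_count(n_relatives, "n_relatives")
  as.integer(ifelse(is.na(n_relatives), 0L, pmin(n_relatives, 2L)))
}

#' Code number of benign breast biopsies
#'
#' The BCDDP model distinguishes 0 / 1 / >= 2 biopsies (codes 0/1/2); all
#' Singapore-calibrated models pool any biopsy history into a single code
#' (0 / >= 1 -> 1).  Unknown -> 0.
#'
#' @param n_biopsies Count of previous benign breast biopsies, `NA` for
#'   unknown.
#' @param model Model identifier selecting the coding scheme.
#' @return Integer codes.
#' @export
code_nbiops <- function(n_biopsies, model = "gail-sbsp") {
  chk_count(n_biopsies, "n_biopsies")
  cap <- if (identical(model, "bcddp")) 2L else 1L
  as.integer(ifelse(is.na(n_biopsies), 0L, pmin(n_biopsies, cap)))
}

#' Code body mass index
#'
#' WHO Asian cut points: < 23.0 -> 0, 23.0-27.4 -> 1, >= 27.5 -> 2;
#' unknown -> 0.
#'
#' @param bmi Body mass index in kg/m^2, `NA` for unknown.
#' @return Integer codes.
#' @export
code_bmi <- function(bmi) {
  chk_positive(bmi, "bmi")
  out <- ifelse(is.na(bmi), 0L,
         ifelse(bmi < 23.0, 0L,
         ifelse(bmi < 27.5, 1L, 2L)))
  as.integer(out)
}

#' Code parity
#'
#' Categories (note the inverted direction: high parity is the referent):
#' >= 3 live births -> 0, 1-2 -> 1, 0 -> 2; unknown -> 0.
#'
#' @param parity Number of live births, `NA` for unknown.
#' @return Integer codes.
#' @export
code_parity <- function(parity) {
  chk_count(parity, "parity")
  out <- ifelse(is.na(parity), 0L,
         ifelse(parity >= 3, 0L,
         ifelse(parity >= 1, 1L, 2L)))
  as.integer(out)
}

chk_positive <- function(x, what) {
  if (any(!is.na(x) & x <= 0))
    stop("'", what, "' must be positive (NA marks unknown)", call. = FALSE)
  invisible(x)
}

chk_count <- function(x, what) {
  if (any(!is.na(x) & (x < 0 | x != round(x))))
    stop("'", what, "' must be a non-negative count (NA marks unknown)",
         call. = FALSE)
  invisible(x)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Code one woman's record into a risk profile
#'
#' Applies every category coder to a raw record and cross-checks internal
#' consistency (a woman recorded nulliparous cannot also report live
#' births).  The biopsy code depends on the model family, so the target
#' model is part of the profile.
#'
#' @param record A list or one-row data frame with fields `entry_age`,
#'   `ethnicity`, `age_menarche`, `age_first_birth`, `nulliparous`,
#'   `n_relatives`, `n_biopsies`, `atypical`, `bmi`, `parity`, and
#'   optionally `id` and `case_status`.  Missing fields are treated as
#'   unknown.
#' @param model Model identifier the profile will be evaluated under.
#' @return An object of class `risk_profile` holding the integer category
#'   codes, `agecat` (1 if entry age >= 50), entry age and ethnicity.
#' @examples
#' make_profile(list(entry_age = 55, age_menarche = 13,
#'                   age_first_birth = 26, n_relatives = 1))
#' @export
make_profile <- function(record, model = "gail-sbsp") {
  if (inherits(record, "risk_profile")) {
    # coding is idempotent: a coded profile passes through untouched, but
    # the biopsy code cannot be widened from the pooled to the BCDDP scheme
    if (identical(model == "bcddp", record$model == "bcddp")) {
      record$model <- model
      return(record)
    }
    stop("profile was coded under the '", record$model, "' biopsy scheme; ",
         "recode from the raw record for '", model, "'", call. = FALSE)
  }
  record <- as.list(record)
  g <- function(f) if (is.null(record[[f]]) || length(record[[f]]) == 0)
    NA else record[[f]]
  entry_age <- g("entry_age")
  if (is.na(entry_age) || entry_age < 20 || entry_age >= 85)
    stop("entry_age must be known and lie in [20, 85)", call. = FALSE)
  nulli <- isTRUE_vec(g("nulliparous"))
  parity <- g("parity")
  aflb <- g("age_first_birth")
  if (nulli && !is.na(parity) && parity > 0)
    stop("contradictory record: nulliparous with parity ", parity,
         call. = FALSE)
  if (nulli && !is.na(aflb))
    stop("contradictory record: nulliparous with an age at first birth",
         call. = FALSE)
  if (!is.na(parity) && parity == 0 && !is.na(aflb))
    stop("contradictory record: parity 0 with an age at first birth",
         call. = FALSE)
  # parity 0 implies nulliparity for the ageflb coder
  if (!nulli && !is.na(parity) && parity == 0) nulli <- TRUE
  if (nulli && is.na(parity)) parity <- 0
  atyp <- g("atypical")
  out <- list(
    id = if (is.na(g("id")[1])) NA_character_ else as.character(g("id")),
    model = model,
    entry_age = as.numeric(entry_age),
    ethnicity = if (is.na(g("ethnicity")[1])) "unknown"
                else as.character(g("ethnicity")),
    agecat = as.integer(entry_age >= 50),
    agemen = code_agemen(g("age_menarche")),
    ageflb = code_ageflb(aflb, nulliparous = nulli),
    numrel = code_numrel(g("n_relatives")),
    nbiops = code_nbiops(g("n_biopsies"), model = model),
    atypical = if (is.na(atyp)) NA_integer_ else as.integer(as.logical(atyp)),
    bmi = code_bmi(g("bmi")),
    parity = code_parity(parity),
    case_status = if (is.na(g("case_status")[1])) NA_integer_
                  else as.integer(g("case_status"))
  )
  class(out) <- "risk_profile"
  out
}

#' Code a whole cohort
#'
#' Vectorized [make_profile()]: takes a raw cohort data frame (see
#' [read_cohort()] for the column contract) and appends the integer
#' category-code columns `agecat`, `agemen`, `ageflb`, `numrel`, `nbiops`,
#' `bmi_code`, `parity_code` plus an `atypical` indicator.
#'
#' @param cohort Data frame of raw records, one row per woman.
#' @param model Model identifier (controls the biopsy coding).
#' @return The cohort with code columns appended and attribute
#'   `coded_model` set.
#' @export
code_cohort <- function(cohort, model = "gail-sbsp") {
  stopifnot(is.data.frame(cohort))
  need <- function(f) if (f %in% names(cohort)) cohort[[f]] else
    rep(NA, nrow(cohort))
  age <- need("entry_age")
  if (any(is.na(age) | age < 20 | age >= 85))
    stop("entry_age must be known and lie in [20, 85) for every row",
         call. = FALSE)
  nulli <- isTRUE_vec(need("nulliparous"))
  parity <- need("parity")
  aflb <- need("age_first_birth")
  bad <- which(nulli & !is.na(parity) & parity > 0)
  if (length(bad))
    stop("contradictory record (nulliparous with parity > 0) at row ",
         bad[1], call. = FALSE)
  bad <- which((nulli | (!is.na(parity) & parity == 0)) & !is.na(aflb))
  if (length(bad))
    stop("contradictory record (no live births but an age at first birth) ",
         "at row ", bad[1], call. = FALSE)
  nulli <- nulli | (!is.na(parity) & parity == 0)
  parity[nulli & is.na(parity)] <- 0
  atyp <- need("atypical")
  cohort$agecat <- as.integer(age >= 50)
  cohort$agemen <- code_agemen(need("age_menarche"))
  cohort$ageflb <- code_ageflb(aflb, nulliparous = nulli)
  cohort$numrel <- code_numrel(need("n_relatives"))
  cohort$nbiops <- code_nbiops(need("n_biopsies"), model = model)
  cohort$atypical <- ifelse(is.na(atyp), NA_integer_,
                            as.integer(as.logical(atyp)))
  cohort$bmi_code <- code_bmi(need("bmi"))
  cohort$parity_code <- code_parity(parity)
  if (!"ethnicity" %in% names(cohort)) cohort$ethnicity <- "unknown"
  cohort$ethnicity[is.na(cohort$ethnicity)] <- "unknown"
  attr(cohort, "coded_model") <- model
  cohort
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("Risk profile", if (!is.na(x$id)) paste0("(", x$id, ")"), "\n")
  cat("  entry age ", x$entry_age, " (agecat ", x$agecat, "), ethnicity ",
      x$ethnicity, "\n", sep = "")
  cat("  codes: agemen", x$agemen, "ageflb", x$ageflb, "numrel", x$numrel,
      "nbiops", x$nbiops, "bmi", x$bmi, "parity", x$parity,
      "atypical", if (is.na(x$atypical)) "unknown" else x$atypical, "\n")
  invisible(x)
}
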