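# ---------------------------------------------------------------------------
# Cohort CSV I/O.
#
# One row per woman.  Recognised columns (extra columns pass through):
#   id, entry_age, ethnicity, age_menarche, age_first_birth, n_relatives,
#   n_biopsies, atypical, bmi, parity, case_status
# Unknown values are empty cells or NA; age_first_birth additionally
# accepts the literal "nulliparous".  Lines starting with '#' are header
# comments written by the command-line tools and are skipped on read.
# ---------------------------------------------------------------------------

#' Read a cohort CSV
#'
#' @param path File path.
#' @return Data frame of raw records with a logical `nulliparous` column
#'   split out of `age_first_birth`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("no rows in cohort file: ", path, call. = FALSE)
  if ("age_first_birth" %in% names(df) &&
      !"nulliparous" %in% names(df)) {
    v <- as.character(df$age_first_birth)
    df$nulliparous <- !is.na(v) & tolower(v) == "nulliparous"
    df$age_first_birth <- suppressWarnings(as.numeric(v))
  }
  df
}

#' Write a cohort CSV
#'
#' Nulliparity is folded back into the `age_first_birth` column as the
#' literal `"nulliparous"` so files round-trip through [read_cohort()].
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @param header Optional character vector of comment lines (written
#'   prefixed with `# `).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, header = NULL) {
  out <- cohort
  if ("nulliparous" %in% names(out)) {
    afb <- as.character(out$age_first_birth)
    afb[isTRUE_vec(out$nulliparous)] <- "nulliparous"
    out$age_first_birth <- afb
    out$nulliparous <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste("#", header), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
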