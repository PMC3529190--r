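# ---------------------------------------------------------------------------
# Calibration and discrimination machinery.
#
# Calibration compares the expected case count E (the sum of individual
# predicted risks) with the observed count O via the ratio E/O, the
# log-scale interval (E/O) exp(+-1.96 sqrt(1/O)), and the goodness-of-fit
# statistic sum (O - E)^2 / E referred to a chi-square with k degrees of
# freedom, k being the number of categories.  df = k (not the usual k - 1)
# is deliberate: the expected counts come from an externally specified
# model, not from parameters fitted to the grouped data, and only df = k
# reproduces the published p-values this implementation is checked against.
# ---------------------------------------------------------------------------

#' Expected number of cases
#'
#' @param predicted_risks Individual predicted probabilities in `[0, 1]`.
#' @return Their sum.
#' @export
expected_cases <- function(predicted_risks) {
  if (any(is.na(predicted_risks)) ||
      any(predicted_risks < 0 | predicted_risks > 1))
    stop("predicted risks must lie in [0, 1]", call. = FALSE)
  sum(predicted_risks)
}

#' Expected/observed ratio with log-scale confidence interval
#'
#' `ratio = E / O` with bounds `ratio * exp(-+ z sqrt(1/O))`.  For the
#' conventional 95% level `z` is fixed at 1.96 rather than taken from a
#' quantile call, so intervals reproduce published tables digit for digit.
#' With no observed case the ratio and interval are undefined and returned
#' as `NA` (tables print a dash).
#'
#' @param E Expected count (>= 0).
#' @param O Observed count (non-negative integer).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(ratio, lower, upper)`.
#' @examples
#' eo_ratio_ci(241.83, 241)   # 1.00 (0.88 to 1.14)
#' @export
eo_ratio_ci <- function(E, O, level = 0.95) {
  if (length(E) != 1 || length(O) != 1 || is.na(E) || is.na(O) ||
      E < 0 || O < 0 || O != round(O))
    stop("'E' must be a non-negative number and 'O' a non-negative integer",
         call. = FALSE)
  if (O == 0)
    return(c(ratio = NA_real_, lower = NA_real_, upper = NA_real_))
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  ratio <- E / O
  half <- z * sqrt(1 / O)
  c(ratio = ratio, lower = ratio * exp(-half), upper = ratio * exp(half))
}

#' Chi-square goodness of fit of grouped expected counts
#'
#' @param O Observed counts per category.
#' @param E Expected counts per category, all strictly positive (merge
#'   empty categories upstream).
#' @return Named vector `c(chisq, df, p)` with `df` equal to the number of
#'   categories.
#' @examples
#' goodness_of_fit(c(0, 144, 95, 2), c(0.95, 124.11, 115.38, 1.40))
#' @export
goodness_of_fit <- function(O, E) {
  if (length(O) != length(E) || length(O) < 1)
    stop("'O' and 'E' must be equal-length, non-empty", call. = FALSE)
  if (any(is.na(O)) || any(is.na(E)) || any(O < 0))
    stop("counts must be non-negative and known", call. = FALSE)
  if (any(E <= 0))
    stop("every expected count must be positive; merge empty categories ",
         "before testing", call. = FALSE)
  chisq <- sum((O - E)^2 / E)
  df <- length(O)
  c(chisq = chisq, df = df,
    p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Grouped calibration report for a cohort
#'
#' Predicts every woman's risk, groups the cohort, and compares expected
#' with observed cases per group: `E` is the sum of predicted risks, `O`
#' the sum of case statuses, the ratio and interval come from
#' [eo_ratio_ci()], and the overall fit from [goodness_of_fit()] across the
#' groups with positive expectation.
#'
#' @param cohort Cohort data frame with a `case_status` column (0/1 over
#'   the follow-up horizon).
#' @param coeffs A [coefficient_set()].
#' @param rates Rates specification as in [predict_cohort()].
#' @param group_by One of `"age-band"`, `"agemen"`, `"ageflb"`, `"numrel"`,
#'   `"nbiops"`, `"bmi"`, `"parity"`, `"ethnicity"`, or `"none"` for a
#'   single whole-cohort group.
#' @param age_bands Left-closed band edges in years used when grouping by
#'   age band (default `c(45, 50, 60, 70, 75)` giving 45-49, 50-59, 60-69,
#'   70-74).
#' @param horizon Projection horizon in years.
#' @return An object of class `calibration_report`: a `groups` data frame
#'   (label, n, O, E, ratio, lower, upper) and an `overall` goodness-of-fit
#'   vector.
#' @export
group_calibration <- function(cohort, coeffs, rates = "sg-ethnic",
                              group_by = "age-band",
                              age_bands = c(45, 50, 60, 70, 75),
                              horizon = 5) {
  if (!"case_status" %in% names(cohort) || any(is.na(cohort$case_status)))
    stop("every woman needs a known case_status", call. = FALSE)
  pred <- predict_cohort(cohort, coeffs, rates, horizon = horizon)
  grp <- switch(group_by,
    "none" = factor(rep("total", nrow(pred))),
    "age-band" = cut(pred$entry_age, breaks = age_bands, right = FALSE,
                     labels = paste0(age_bands[-length(age_bands)], "-",
                                     age_bands[-1] - 1)),
    "agemen" = , "ageflb" = , "numrel" = , "nbiops" = factor(pred[[group_by]]),
    "bmi" = factor(pred$bmi_code),
    "parity" = factor(pred$parity_code),
    "ethnicity" = factor(pred$ethnicity),
    stop("unknown grouping '", group_by, "'", call. = FALSE))
  if (any(is.na(grp)))
    stop("grouping leaves ", sum(is.na(grp)), " women unassigned ",
         "(entry age outside the age bands?)", call. = FALSE)
  keep <- levels(grp)[tabulate(grp, nbins = nlevels(grp)) > 0]
  if (length(keep) < nlevels(grp))
    message("dropping empty group(s): ",
            paste(setdiff(levels(grp), keep), collapse = ", "))
  grp <- factor(grp, levels = keep)
  E <- as.numeric(tapply(pred$p_breast_cancer, grp, sum))
  O <- as.numeric(tapply(pred$case_status, grp, sum))
  n <- as.numeric(table(grp))
  ci <- t(mapply(function(e, o) eo_ratio_ci(e, o), E, O))
  groups <- data.frame(group = keep, n = n, O = O, E = E,
                       ratio = ci[, "ratio"], lower = ci[, "lower"],
                       upper = ci[, "upper"])
  pos <- E > 0
  overall <- goodness_of_fit(O[pos], E[pos])
  structure(list(groups = groups, overall = overall, group_by = group_by,
                 model = coeffs$model),
            class = "calibration_report")
}

#' Concordance (AUC) with Hanley-McNeil variance
#'
#' Rank-based estimate of the probability that a randomly chosen case
#' received a higher predicted risk than a randomly chosen non-case, with
#' midranks for ties (equivalent to the trapezoidal area under the ROC
#' curve).  The variance is the Hanley-McNeil approximation; an exact
#' permutation option is deliberately not provided here because the bands
#' this is applied to are large.
#'
#' @param predicted Numeric risk scores.
#' @param status 0/1 case indicators, same length; both classes must be
#'   present.
#' @return Named vector `c(auc, variance)`.
#' @examples
#' auc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))  # 0.75
#' @export
auc <- function(predicted, status) {
  if (length(predicted) != length(status) || any(is.na(predicted)) ||
      any(is.na(status)))
    stop("'predicted' and 'status' must be equal-length and known",
         call. = FALSE)
  if (!all(status %in% c(0, 1)))
    stop("'status' must be 0/1", call. = FALSE)
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  if (n1 == 0 || n0 == 0)
    stop("concordance needs at least one case and one non-case",
         call. = FALSE)
  r <- rank(predicted)  # midranks
  A <- (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  v <- (A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n0 - 1) * (q2 - A^2)) /
    (n1 * n0)
  c(auc = A, variance = v)
}

#' Weighted age-specific concordance
#'
#' Computes the concordance statistic within each age band, then averages
#' with weights proportional to band size (renormalised over the bands that
#' contribute).  Bands without any case — or without any non-case — cannot
#' yield a concordance and are excluded.  The variance of the average is
#' the sum over bands of squared weight times band variance; the 95%
#' interval uses z = 1.96 and is truncated to `[0, 1]`.
#'
#' @inheritParams group_calibration
#' @return An object of class `concordance_report`: a `bands` data frame
#'   (band, n, cases, auc, variance, weight) and `estimate`, `variance`,
#'   `lower`, `upper` for the weighted average.
#' @export
weighted_concordance <- function(cohort, coeffs, rates = "sg-ethnic",
                                 age_bands = c(45, 50, 60, 70, 75),
                                 horizon = 5) {
  if (!"case_status" %in% names(cohort) || any(is.na(cohort$case_status)))
    stop("every woman needs a known case_status", call. = FALSE)
  pred <- predict_cohort(cohort, coeffs, rates, horizon = horizon)
  band <- cut(pred$entry_age, breaks = age_bands, right = FALSE,
              labels = paste0(age_bands[-length(age_bands)], "-",
                              age_bands[-1] - 1))
  if (any(is.na(band)))
    stop("age bands do not cover every entry age", call. = FALSE)
  rows <- lapply(levels(band), function(bl) {
    in_b <- band == bl
    n <- sum(in_b)
    cases <- sum(pred$case_status[in_b])
    usable <- n > 0 && cases > 0 && cases < n
    a <- if (usable)
      auc(pred$p_breast_cancer[in_b], pred$case_status[in_b])
    else c(auc = NA_real_, variance = NA_real_)
    data.frame(band = bl, n = n, cases = cases, auc = a[["auc"]],
               variance = a[["variance"]], included = usable)
  })
  bands <- do.call(rbind, rows)
  inc <- bands$included
  if (!any(inc))
    stop("no age band has both a case and a non-case", call. = FALSE)
  w <- ifelse(inc, bands$n, 0)
  w <- w / sum(w)
  bands$weight <- w
  est <- sum(w[inc] * bands$auc[inc])
  v <- sum(w[inc]^2 * bands$variance[inc])
  structure(list(
    bands = bands[, c("band", "n", "cases", "auc", "variance", "weight")],
    estimate = est, variance = v,
    lower = max(0, est - 1.96 * sqrt(v)),
    upper = min(1, est + 1.96 * sqrt(v)),
    model = coeffs$model), class = "concordance_report")
}

#' Decile calibration table
#'
#' Orders the cohort by predicted risk (stable in input order for ties),
#' splits it into ten near-equal buckets — any remainder goes one extra
#' woman at a time to the lowest deciles — and tabulates mean predicted
#' risk against the observed case proportion per decile.
#'
#' @param predicted Individual predicted risks.
#' @param status 0/1 case indicators.
#' @return Data frame with columns `decile`, `n`, `mean_predicted`,
#'   `observed_proportion`.
#' @export
decile_calibration <- function(predicted, status) {
  n <- length(predicted)
  if (n < 10) stop("decile calibration needs at least 10 women",
                   call. = FALSE)
  if (length(status) != n) stop("length mismatch", call. = FALSE)
  ord <- order(predicted)  # stable: ties keep input order
  sizes <- rep(n %/% 10, 10)
  rem <- n %% 10
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  dec <- rep(1:10, times = sizes)
  p <- predicted[ord]
  s <- status[ord]
  data.frame(
    decile = 1:10,
    n = sizes,
    mean_predicted = as.numeric(tapply(p, dec, mean)),
    observed_proportion = as.numeric(tapply(s, dec, mean)))
}

#' @export
print.calibration_report <- function(x, digits = 2, ...) {
  cat("Calibration report (model ", x$model, ", grouped by ", x$group_by,
      ")\n", sep = "")
  g <- x$groups
  g$`E/O (95% CI)` <- ifelse(
    is.na(g$ratio), "-",
    sprintf("%.*f (%.*f to %.*f)", digits, g$ratio, digits, g$lower,
            digits, g$upper))
  print(g[, c("group", "n", "O", "E", "E/O (95% CI)")], row.names = FALSE)
  cat(sprintf("Goodness of fit: chi-square %.3f on %d df, P = %.3f\n",
              x$overall["chisq"], as.integer(x$overall["df"]),
              x$overall["p"]))
  invisible(x)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Weighted age-specific concordance (model ", x$model, ")\n", sep = "")
  print(x$bands, row.names = FALSE, digits = 4)
  cat(sprintf("Weighted AUC %.4f (95%% CI %.4f to %.4f)\n",
              x$estimate, x$lower, x$upper))
  invisible(x)
}
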