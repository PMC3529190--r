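test_that("expected cases is the sum of predicted risks", {
  expect_equal(expected_cases(numeric(0)), 0)
  expect_equal(expected_cases(c(0.5, 0.5)), 1.0)
  expect_error(expected_cases(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("E/O ratio and CI reproduce the published calibration rows", {
  expect_equal(round(eo_ratio_ci(241.83, 241), 2),
               c(ratio = 1.00, lower = 0.88, upper = 1.14))
  expect_equal(round(eo_ratio_ci(10.16, 17), 2),
               c(ratio = 0.60, lower = 0.37, upper = 0.96))
  # the published inputs for this row are themselves rounded to 2 dp, so
  # the bounds are only reproducible to within that input rounding
  row <- eo_ratio_ci(0.36, 2)
  expect_equal(round(row[["ratio"]], 2), 0.18)
  expect_lt(abs(row[["lower"]] - 0.04), 0.015)
  expect_lt(abs(row[["upper"]] - 0.71), 0.015)
  expect_true(all(is.na(eo_ratio_ci(0.95, 0))))
  expect_error(eo_ratio_ci(-1, 3), "non-negative")
})

test_that("E/O bounds are symmetric on the log scale", {
  for (E in c(0.4, 12.3, 241.83)) {
    for (O in c(1, 17, 241)) {
      ci <- eo_ratio_ci(E, O)
      expect_equal(log(ci["upper"]) - log(ci["ratio"]),
                   log(ci["ratio"]) - log(ci["lower"]),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("goodness of fit reproduces the published p-values with df = k", {
  expect_equal(round(goodness_of_fit(241, 241.83)[["p"]], 3), 0.957)
  expect_equal(round(goodness_of_fit(241, 241.80)[["p"]], 3), 0.959)
  expect_equal(round(goodness_of_fit(241, 289.47)[["p"]], 3), 0.004)
  gof <- goodness_of_fit(c(0, 144, 95, 2), c(0.95, 124.11, 115.38, 1.40))
  expect_equal(gof[["df"]], 4)
  expect_equal(round(gof[["p"]], 3), 0.092)
  # expected counts here are printed at 2 dp, which moves the p-value in
  # its third decimal
  expect_lt(abs(goodness_of_fit(
    c(0, 144, 95, 2), c(0.97, 124.86, 114.57, 1.40))[["p"]] - 0.111),
    0.002)
  # perfect fit and permutation invariance
  expect_equal(goodness_of_fit(c(3, 5), c(3, 5))[["p"]], 1)
  o <- c(4, 9, 2)
  e <- c(5.2, 7.7, 3.3)
  prm <- sample(3)
  expect_equal(goodness_of_fit(o, e)[["p"]],
               goodness_of_fit(o[prm], e[prm])[["p"]])
  expect_error(goodness_of_fit(c(1, 2), c(1, 0)), "positive")
})

test_that("group calibration composes prediction, E/O and GOF", {
  coh <- simulate_cohort(3000, seed = 31)
  cs <- builtin_coefficients("s-gail-sbsp")
  whole <- group_calibration(coh, cs, group_by = "none")
  pred <- predict_cohort(coh, cs)
  E <- expected_cases(pred$p_breast_cancer)
  O <- sum(coh$case_status)
  expect_equal(whole$groups$E, E)
  expect_equal(whole$groups$O, O)
  expect_equal(unname(whole$groups$ratio), unname(eo_ratio_ci(E, O)["ratio"]))
  expect_equal(unname(whole$overall["p"]),
               unname(goodness_of_fit(O, E)["p"]))
  # factor grouping partitions E and O
  bynr <- group_calibration(coh, cs, group_by = "numrel")
  expect_equal(sum(bynr$groups$E), E, tolerance = 1e-9)
  expect_equal(sum(bynr$groups$O), O)
  expect_error(group_calibration(coh[, setdiff(names(coh), "case_status")],
                                 cs), "case_status")
})

test_that("self-consistent cohorts show null-like goodness of fit", {
  # generating model == scoring model, so GOF p should rarely be extreme
  ps <- vapply(1:20, function(s) {
    coh <- simulate_cohort(4000, seed = 1000 + s)
    group_calibration(coh, builtin_coefficients("s-gail-sbsp"),
                      group_by = "age-band")$overall[["p"]]
  }, 0)
  expect_gte(sum(ps > 0.01), 19)
})

test_that("auc matches exhaustive pair counting and handles ties", {
  expect_equal(auc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1))[["auc"]], 0.75)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5))[["auc"]], 0.5)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1))[["auc"]], 1.0)
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    pred <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    status <- rbinom(n, 1, 0.4)
    if (sum(status) == 0 || sum(status) == n) next
    expect_equal(auc(pred, status)[["auc"]], pair_count_auc(pred, status))
  }
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "non-case")
})

test_that("auc is invariant under strictly monotone transforms", {
  set.seed(7)
  pred <- runif(60)
  status <- rbinom(60, 1, 0.3)
  base <- auc(pred, status)[["auc"]]
  expect_equal(auc(qlogis(pred), status)[["auc"]], base)
  expect_equal(auc(pred^3, status)[["auc"]], base)
  expect_equal(auc(rank(pred), status)[["auc"]], base)
})

test_that("weighted concordance degenerates to plain auc on one band", {
  coh <- simulate_cohort(4000, seed = 17)
  cs <- builtin_coefficients("s-gail-sbsp")
  one <- weighted_concordance(coh, cs, age_bands = c(45, 75))
  pred <- predict_cohort(coh, cs)
  plain <- auc(pred$p_breast_cancer, pred$case_status)
  expect_equal(one$estimate, plain[["auc"]])
  expect_equal(one$variance, plain[["variance"]])
})

test_that("weighted concordance averages with size weights", {
  coh <- simulate_cohort(6000, seed = 23)
  cs <- builtin_coefficients("s-gail-sbsp")
  rep <- weighted_concordance(coh, cs)
  inc <- !is.na(rep$bands$auc)
  w <- rep$bands$n[inc] / sum(rep$bands$n[inc])
  expect_equal(rep$estimate, sum(w * rep$bands$auc[inc]))
  expect_equal(rep$variance, sum(w^2 * rep$bands$variance[inc]))
  expect_equal(sum(rep$bands$weight), 1)
  # the average lies within the range of included band AUCs
  expect_gte(rep$estimate, min(rep$bands$auc[inc]))
  expect_lte(rep$estimate, max(rep$bands$auc[inc]))
})

test_that("decile calibration splits near-equally with stable ties", {
  d <- decile_calibration(runif(100), rbinom(100, 1, 0.1))
  expect_equal(d$n, rep(10, 100 / 10))
  # remainder goes to the lowest deciles
  d2 <- decile_calibration(runif(103), rbinom(103, 1, 0.1))
  expect_equal(d2$n, c(11, 11, 11, rep(10, 7)))
  d0 <- decile_calibration(runif(50), rep(0, 50))
  expect_true(all(d0$observed_proportion == 0))
  expect_error(decile_calibration(runif(9), rep(0, 9)), "at least 10")
  # mean predicted risk is non-decreasing across deciles
  p <- rexp(500)
  dd <- decile_calibration(p, rbinom(500, 1, 0.2))
  expect_true(all(diff(dd$mean_predicted) >= 0))
})

test_that("deciles of a self-consistent cohort are binomially consistent", {
  coh <- simulate_cohort(30000, seed = 41)
  pred <- predict_cohort(coh, builtin_coefficients("s-gail-sbsp"))
  d <- decile_calibration(pred$p_breast_cancer, pred$case_status)
  se <- sqrt(d$mean_predicted * (1 - d$mean_predicted) / d$n)
  ok <- abs(d$observed_proportion - d$mean_predicted) < 3 * se
  expect_gte(sum(ok), 9)
})
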