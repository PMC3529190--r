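test_that("relative risk of the referent profile is one", {
  for (m in model_names()) {
    p <- profile_with(model = m)
    expect_equal(relative_risk(p, builtin_coefficients(m), agecat = 0), 1)
  }
})

test_that("relative risk reproduces hand-computed linear predictors", {
  s <- builtin_coefficients("s-gail-sbsp")
  expect_equal(round(relative_risk(profile_with(numrel = 2), s), 2), 4.73)
  b <- builtin_coefficients("bcddp")
  p <- profile_with(ageflb = 3, numrel = 2, model = "bcddp")
  expect_equal(relative_risk(p, b, agecat = 0),
               exp(3 * 0.21863 + 2 * 0.95830 + 6 * (-0.19081)))
  # agecat enters the biopsy interaction
  pb <- profile_with(nbiops = 2, model = "bcddp")
  expect_equal(relative_risk(pb, b, agecat = 1),
               exp(0.01081 + 2 * 0.52926 + 2 * (-0.28804)))
  # unknown atypical hyperplasia contributes nothing
  expect_equal(relative_risk(profile_with(model = "bcddp"), b, agecat = 0), 1)
  pa <- profile_with(model = "bcddp")
  pa$atypical <- 1L
  expect_equal(relative_risk(pa, b, agecat = 0), exp(0.57405))
})

test_that("biopsy-scheme mismatches between profile and model are rejected", {
  p <- profile_with(model = "gail-sbsp")
  expect_error(relative_risk(p, builtin_coefficients("bcddp")),
               "incompatible")
  # models without a biopsy term accept either scheme
  expect_silent(relative_risk(p, builtin_coefficients("s-gail-sbsp"),
                              agecat = 0))
})

test_that("baseline hazard deflates incidence by the attributable risk", {
  cauc <- builtin_rate_table("caucasian-1983-87")
  b <- builtin_coefficients("bcddp")
  expect_equal(baseline_hazard(cauc, b, 7, agecat = 0),
               186.6 * (1 - 0.4771) / 1e5, tolerance = 1e-12)
  expect_equal(baseline_hazard(flat_rates(0, 50), b, 3), 0)
  expect_equal(baseline_hazard(cauc, null_coeffs(), 7), 186.6 / 1e5)
  expect_error(baseline_hazard(cauc, b, 16), "out of range")
})

test_that("single constant-hazard interval matches the closed form", {
  # with r = 1 and AR = 0, P = b/(b+c) (1 - exp(-h (b+c)))
  p <- profile_with(entry_age = 50)
  for (B in c(50, 200, 1000)) {
    for (cc in c(0, 100, 5000)) {
      rt <- flat_rates(B, cc)
      pr <- absolute_risk(p, null_coeffs(), rt, a = 50, h = 5)
      b <- B / 1e5
      k <- cc / 1e5
      expect_equal(pr$p_breast_cancer,
                   b / (b + k) * (1 - exp(-5 * (b + k))),
                   tolerance = 1e-12)
    }
  }
})

test_that("zero incidence over the horizon gives zero risk", {
  p <- profile_with(entry_age = 40)
  pr <- absolute_risk(p, null_coeffs(), flat_rates(0, 300), a = 40, h = 10)
  expect_equal(pr$p_breast_cancer, 0)
  expect_lt(pr$p_event_free, 1)
})

test_that("with no competing mortality risk equals 1 - exp(-sum b r delta)", {
  rt <- builtin_rate_table("sg-chinese")
  rt$intervals$mortality[] <- 0
  p <- profile_with(entry_age = 47, agemen = 1)
  cs <- builtin_coefficients("s-gail-sbsp")
  pr <- absolute_risk(p, cs, rt, a = 47, h = 20)
  expect_equal(pr$p_breast_cancer,
               1 - exp(-sum(pr$trace$exposure * pr$trace$hazard_bc)),
               tolerance = 1e-12)
  expect_equal(pr$p_other_death, 0)
})

test_that("risk vanishes as competing mortality dominates", {
  p <- profile_with(entry_age = 50)
  risks <- vapply(c(1e3, 1e5, 1e9), function(cc)
    absolute_risk(p, null_coeffs(), flat_rates(200, cc),
                  a = 50, h = 5)$p_breast_cancer, 0)
  expect_true(all(diff(risks) < 0))
  expect_lt(risks[3], 1e-6)
})

test_that("probability decomposition sums to one across the model grid", {
  combos <- expand.grid(agemen = 0:2, ageflb = c(0, 3), numrel = 0:2)
  ages <- c(45, 47, 50, 58, 63, 74)
  for (m in c("s-gail-sbsp", "e-gail-sbsp", "gail-sbsp")) {
    cs <- builtin_coefficients(m)
    for (pop in rate_populations()) {
      rt <- builtin_rate_table(pop)
      for (a in ages) {
        for (i in seq_len(nrow(combos))) {
          p <- profile_with(entry_age = a, agemen = combos$agemen[i],
                            ageflb = combos$ageflb[i],
                            numrel = combos$numrel[i])
          pr <- absolute_risk(p, cs, rt, a = a, h = 5)
          expect_lt(abs(pr$p_breast_cancer + pr$p_other_death +
                          pr$p_event_free - 1), 1e-12)
        }
      }
    }
  }
})

test_that("risk is increasing in relative risk and horizon", {
  rt <- builtin_rate_table("sg-overall")
  risks <- vapply(0:2, function(nr)
    absolute_risk(profile_with(entry_age = 52, numrel = nr),
                  builtin_coefficients("s-gail-sbsp"), rt,
                  a = 52, h = 5)$p_breast_cancer, 0)
  expect_true(all(diff(risks) > 0))
  p <- profile_with(entry_age = 52)
  horizons <- vapply(c(1, 3, 5, 10, 20),
                     function(h) absolute_risk(
                       p, builtin_coefficients("s-gail-sbsp"), rt,
                       a = 52, h = h)$p_breast_cancer, 0)
  expect_true(all(diff(horizons) > 0))
})

test_that("interval-sum evaluation agrees with fine-grid integration", {
  # 50 random parameter draws: random rates, codes, entry age, horizon;
  # oracle rebuilds hazards from first principles and integrates the
  # cause-specific density on a 1e-4-year grid
  set.seed(421)
  rt0 <- builtin_rate_table("sg-overall")
  lo <- c(0, rt0$intervals$tau[-15])
  cs <- builtin_coefficients("s-gail-sbsp")
  for (rep in 1:50) {
    B <- runif(15, 0, 400)
    cc <- runif(15, 0, 4000)
    rt <- rate_table("draw", B, cc)
    a <- runif(1, 20, 84)
    h <- runif(1, 0.5, min(5, 90 - a))
    codes <- c(agemen = sample(0:2, 1), ageflb = sample(0:3, 1),
               numrel = sample(0:2, 1))
    p <- profile_with(entry_age = floor(a), agemen = codes["agemen"],
                      ageflb = codes["ageflb"], numrel = codes["numrel"])
    r <- exp(sum(c(0.238, 0.183, 0.777) * codes))
    ar <- ifelse(lo >= 50, 0.4736, 0.4771)
    hb <- B * (1 - ar) * r / 1e5
    hc <- cc / 1e5
    got <- absolute_risk(p, cs, rt, a = a, h = h)$p_breast_cancer
    want <- integrate_risk(a, h, lo, hb, hc)
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("generalised exposures reduce to the aligned 5-year projection", {
  # manual evaluation of the boundary-aligned sum with the printed factor 5
  cs <- builtin_coefficients("gail-sbsp")
  rt <- builtin_rate_table("sg-chinese")
  p <- profile_with(entry_age = 50, agemen = 2, numrel = 1,
                    model = "gail-sbsp")
  r1 <- relative_risk(p, cs, agecat = 1)
  j <- 8  # ages 50-54
  b <- rt$intervals$incidence[j] * (1 - 0.4736) * r1 / 1e5
  cc <- rt$intervals$mortality[j] / 1e5
  manual <- b / (b + cc) * (1 - exp(-5 * (b + cc)))
  expect_equal(absolute_risk(p, cs, rt, a = 50, h = 5)$p_breast_cancer,
               manual, tolerance = 1e-14)
})

test_that("relative risk switches at the age-50 boundary mid-projection", {
  # a horizon crossing 50 must use r0 before and r1 after; with the
  # biopsy-age interaction the two differ
  cs <- builtin_coefficients("gail-sbsp")
  rt <- builtin_rate_table("sg-overall")
  p <- profile_with(entry_age = 48, nbiops = 1, model = "gail-sbsp")
  pr <- absolute_risk(p, cs, rt, a = 48, h = 4)
  expect_false(isTRUE(all.equal(pr$r_under50, pr$r_50plus)))
  # piecewise manual evaluation over [48,50) then [50,52)
  b7 <- rt$intervals$incidence[7] * (1 - 0.4771) * pr$r_under50 / 1e5
  c7 <- rt$intervals$mortality[7] / 1e5
  b8 <- rt$intervals$incidence[8] * (1 - 0.4736) * pr$r_50plus / 1e5
  c8 <- rt$intervals$mortality[8] / 1e5
  manual <- b7 / (b7 + c7) * (1 - exp(-2 * (b7 + c7))) +
    exp(-2 * (b7 + c7)) * b8 / (b8 + c8) * (1 - exp(-2 * (b8 + c8)))
  expect_equal(pr$p_breast_cancer, manual, tolerance = 1e-14)
})

test_that("projections outside the table support are refused", {
  p <- profile_with(entry_age = 84)
  cs <- builtin_coefficients("s-gail-sbsp")
  rt <- builtin_rate_table("sg-overall")
  expect_error(absolute_risk(p, cs, rt, a = 86, h = 5), "support")
  expect_error(absolute_risk(p, cs, rt, a = 84, h = 0), "positive")
  expect_error(absolute_risk(p, cs, rt, a = 15, h = 5), "at least 20")
})

test_that("rr_table reproduces the published grid within rounding", {
  for (m in names(published_rr)) {
    tab <- rr_table(builtin_coefficients(m))
    expect_equal(nrow(tab), length(published_rr[[m]]))
    expect_true(all(abs(tab$rr_exact - published_rr[[m]]) <= 0.015),
                label = paste("grid of", m))
  }
})

test_that("predict_cohort agrees with scalar absolute_risk", {
  coh <- sample_profiles(40, seed = 11)
  cs <- builtin_coefficients("e-gail-sbsp")
  pred <- predict_cohort(coh, cs, rates = "sg-ethnic", horizon = 5)
  for (i in c(1, 7, 23, 40)) {
    p <- make_profile(as.list(coh[i, ]), model = cs$model)
    pop <- switch(p$ethnicity, chinese = "sg-chinese", malay = "sg-malay",
                  indian = "sg-indian", "sg-overall")
    pr <- absolute_risk(p, cs, pop, a = p$entry_age, h = 5)
    expect_equal(pred$p_breast_cancer[i], pr$p_breast_cancer,
                 tolerance = 1e-12)
    expect_equal(pred$r_under50[i], pr$r_under50, tolerance = 1e-12)
  }
})
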