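test_that("synthetic life table behaves like a period life table", {
  lt <- generate_life_table()
  # closure and bounds
  expect_equal(lt$q_all_cause[lt$age == 110], c(1, 1))
  expect_true(all(lt$q_all_cause >= 0 & lt$q_all_cause <= 1))
  expect_true(all(lt$ihd_fraction >= 0 & lt$ihd_fraction < 1))
  # q non-decreasing above age 30, male excess at every age
  for (sx in c("male", "female")) {
    q <- lt$q_all_cause[lt$sex == sx & lt$age >= 30]
    expect_true(all(diff(q) >= 0))
  }
  qm <- lt$q_all_cause[lt$sex == "male"]
  qf <- lt$q_all_cause[lt$sex == "female"]
  expect_true(all(qm >= qf))
  # life expectancy at birth: independent discrete oracle sum of survival
  q <- lt$q_all_cause[lt$sex == "female"]
  oracle_e0 <- sum(cumprod(1 - q)) + 0.5
  expect_equal(life_expectancy(lt, 0, "female"), oracle_e0)
  expect_gt(oracle_e0, 75)
  expect_lt(oracle_e0, 85)
  expect_true(is.finite(life_expectancy(lt, 40, "male")))
})

test_that("degenerate life-table limits behave as expected", {
  # pure age-independent hazard: constant q (geometric survival) until closure
  m <- 0.01
  lt <- generate_life_table(makeham_a = m, gompertz_b = 1e-300,
                            gompertz_c = 1.1)
  q <- lt$q_all_cause[lt$sex == "female" & lt$age < 110]
  expect_equal(q, rep(m, 110), tolerance = 1e-12)
  # no IHD fraction: cause-deleted equals all-cause
  lt0 <- generate_life_table(ihd_peak_fraction = 0)
  expect_equal(cause_deleted_mortality(lt0, 70, "male"),
               all_cause_mortality(lt0, 70, "male"))
  # hazards exceeding 1 before age 100 are rejected
  expect_error(generate_life_table(makeham_a = 0.5, gompertz_b = 0.1,
                                   gompertz_c = 1.2),
               "q > 1")
})

test_that("cause-deleted mortality removes exactly the IHD share", {
  tab <- structure(data.frame(age = c(50, 50), sex = c("female", "male"),
                              q_all_cause = c(0.02, 0.02),
                              ihd_fraction = c(0.25, 0)),
                   class = c("baricea_life_table", "data.frame"))
  expect_equal(cause_deleted_mortality(tab, 50, "female"), 0.015)
  expect_equal(cause_deleted_mortality(tab, 50, "male"), 0.02)
  expect_error(cause_deleted_mortality(tab, 60, "male"), "outside")
  # additivity oracle over a whole generated table: deleted + subtracted
  lt <- generate_life_table()
  deleted <- lt$q_all_cause * (1 - lt$ihd_fraction)
  subtracted <- lt$q_all_cause * lt$ihd_fraction
  expect_equal(deleted + subtracted, lt$q_all_cause, tolerance = 1e-15)
  expect_true(all(deleted <= lt$q_all_cause))
})

test_that("life-table text round trip preserves the table", {
  lt <- generate_life_table(seed = 3)
  f <- tempfile(fileext = ".tsv")
  write_life_table(lt, f)
  back <- read_life_table(f)
  expect_equal(back$q_all_cause, lt$q_all_cause, tolerance = 1e-12)
  expect_equal(back$ihd_fraction, lt$ihd_fraction, tolerance = 1e-12)
  # seeded noise is deterministic given parameters and seed
  expect_identical(generate_life_table(seed = 3)$q_all_cause, lt$q_all_cause)
})

test_that("placeholder risk equations hit their calibration anchors", {
  coeffs <- default_risk_coefficients(ref_params)
  # intercept-only limit: all slopes zero
  zero <- default_risk_coefficients(
    ref_params,
    slopes = stats::setNames(rep(list(rep(0, 6)), 6),
                             c("angina", "mi", "stroke", "hf", "pad", "tia")))
  p_ann <- event_probability("mi", ref_prof, coeffs = zero, per = "year")
  expect_equal(p_ann, plogis(zero$intercepts[["mi"]]))
  # annual risk at the calibration profile equals the static target
  expect_equal(event_probability("mi", ref_prof, coeffs = coeffs,
                                 per = "year"),
               1 - (1 - 0.06)^(1 / 10), tolerance = 1e-12)

  # comorbidity amplification: heart failure doubles stroke risk on the
  # annual scale (before monthly conversion), with the configured RR = 2
  r0 <- event_probability("stroke", ref_prof, coeffs = coeffs, per = "year")
  r1 <- event_probability("stroke", ref_prof, existing = "hf",
                          coeffs = coeffs, per = "year")
  expect_equal(r1 / r0, param_value(ref_params, "rr_stroke_given_hf"),
               tolerance = 1e-12)
  expect_error(event_probability("stroke", ref_prof, existing = "gout",
                                 coeffs = coeffs), "unknown condition")
  expect_error(event_probability("appendicitis", ref_prof, coeffs = coeffs),
               "unknown event")
})

test_that("event risk is monotone in SBP, BMI, age, diabetes and smoking", {
  coeffs <- default_risk_coefficients(ref_params)
  grid_sbp <- seq(140, 180, by = 10)
  for (ev in c("angina", "mi", "stroke", "hf", "pad", "tia")) {
    risks <- vapply(grid_sbp, function(s) {
      pr <- cohort_profile(50, 1, 40, s, 0, 0)
      event_probability(ev, pr, coeffs = coeffs)
    }, numeric(1))
    expect_true(all(diff(risks) >= 0), info = ev)
  }
  base <- cohort_profile(50, 1, 35, 140, 0, 0)
  riskier <- list(
    cohort_profile(60, 1, 35, 140, 0, 0),   # older
    cohort_profile(50, 1, 45, 140, 0, 0),   # heavier
    cohort_profile(50, 1, 35, 140, 1, 0),   # diabetic
    cohort_profile(50, 1, 35, 140, 0, 1)    # smoker
  )
  for (pr in riskier) {
    expect_gte(event_probability("mi", pr, coeffs = coeffs),
               event_probability("mi", base, coeffs = coeffs))
  }
})

test_that("diabetes incidence rises log-linearly with BMI", {
  coeffs <- default_risk_coefficients(ref_params)
  rr <- param_value(ref_params, "t2d_rr_per_bmi_unit")
  expect_equal(t2d_incidence_annual(35, coeffs) / t2d_incidence_annual(30, coeffs),
               rr^5, tolerance = 1e-10)
  # monotone in BMI: a BMI-52 cohort outranks a BMI-33 cohort
  expect_gt(t2d_incidence_annual(52, coeffs), t2d_incidence_annual(33, coeffs))
  # doubling the BMI slope widens that gap
  steep <- coeffs
  steep$t2d$rr_per_bmi_unit <- rr^2
  expect_gt(t2d_incidence_annual(52, steep) / t2d_incidence_annual(33, steep),
            t2d_incidence_annual(52, coeffs) / t2d_incidence_annual(33, coeffs))
})

test_that("cohort fixtures reproduce the baseline distributions", {
  fix <- generate_cohort_fixture(n = 10000, seed = 11, params = ref_params)
  expect_equal(nrow(fix), 10000)
  # sample means within 3 SE of the reference point estimates
  expect_lt(abs(mean(fix$age) - 40.4), 3 * 4.04 / sqrt(10000))
  expect_lt(abs(mean(fix$bmi) - 48.8), 3 * 6.5 / sqrt(10000))
  expect_lt(abs(mean(fix$male) - 0.263),
            3 * sqrt(0.263 * 0.737 / 10000))
  expect_lt(abs(mean(fix$diabetic) - 0.206),
            3 * sqrt(0.206 * 0.794 / 10000))
  expect_lt(abs(mean(fix$sbp) - 140.1),
            3 * sqrt(55.53) * 2.52 / sqrt(10000) + abs(140.1 - 55.53 * 2.52))
  # reproducibility and single-row bounds
  expect_identical(fix, generate_cohort_fixture(n = 10000, seed = 11,
                                                params = ref_params))
  one <- generate_cohort_fixture(n = 1, seed = 5, params = ref_params)
  expect_equal(nrow(one), 1)
  expect_true(one$age >= 18 && one$age <= 100)
  expect_true(one$bmi >= 20 && one$bmi <= 80)
  expect_true(one$sbp >= 90 && one$sbp <= 250)
})
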