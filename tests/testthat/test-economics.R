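test_that("discounting follows the annual-step convention", {
  # rate zero: plain sum
  s <- runif(30)
  expect_equal(discount_series(s, discount_spec(0)), sum(s))
  # hand computation: 100 euros at month 6 undiscounted, at month 18 one
  # annual step
  s2 <- numeric(18); s2[6] <- 100; s2[18] <- 100
  expect_equal(discount_series(s2, discount_spec(0.03)), 100 + 100 / 1.03)
  # the step starts exactly at month 13
  s3 <- numeric(13); s3[13] <- 1
  expect_equal(discount_series(s3, discount_spec(0.03)), 1 / 1.03)
  # totals are non-increasing in the rate; discounted <= undiscounted
  rates <- c(0, 0.01, 0.03, 0.05, 0.10)
  tot <- vapply(rates, function(r) discount_series(s, discount_spec(r)),
                numeric(1))
  expect_true(all(diff(tot) <= 0))
  # monthly-compounding variant stays below the step convention's total
  expect_lte(discount_series(s2, discount_spec(0.03, "monthly")),
             discount_series(s2, discount_spec(0.03)))
  expect_error(discount_spec(-0.01), ">= 0")
})

# a context where the whole cohort sits in the diabetic comparator state
# with (numerically) no mortality and no cardiovascular risk, so state
# costs and utilities can be checked by arithmetic
quiet_ctx <- function(profile, horizon = 12L) {
  p <- ref_params
  p$parameters$lt_makeham_a$value <- 1e-12
  p$parameters$lt_gompertz_b$value <- 1e-300
  for (nm in c("cost_visit_gp", "cost_visit_dietician")) {
    p$parameters[[nm]]$value <- 0
    p$parameters[[nm]]$low <- 0
  }
  quiet <- default_risk_coefficients(
    p, target_10y = c(angina = 1e-12, mi = 1e-12, stroke = 1e-12,
                      hf = 1e-12, pad = 1e-12, tia = 1e-12))
  quiet$t2d$incidence_bmi25 <- 0
  model_context(p, profile, arm = "CMM", horizon_months = horizon,
                coeffs = quiet)
}

test_that("a full diabetic year accrues exactly the annual diabetes cost", {
  prof <- cohort_profile(40.4, 0.263, 48.8, 140.1, diabetic = 1, smoker = 0.219)
  run <- simulate_arm(quiet_ctx(prof))
  cost <- accrue_costs(run)
  expect_equal(sum(cost), param_value(ref_params, "cost_t2d_annual"),
               tolerance = 1e-6)
})

test_that("QALY accrual reproduces the additive utility arithmetic", {
  prof_heavy <- cohort_profile(40.4, 0.263, 48.8, 140.1, 0, 0.219)
  prof_light <- cohort_profile(40.4, 0.263, 35.0, 140.1, 0, 0.219)
  q_heavy <- accrue_qalys(simulate_arm(quiet_ctx(prof_heavy)))
  q_light <- accrue_qalys(simulate_arm(quiet_ctx(prof_light)))
  # per-cycle utility difference = BMI decrement x (48.8 - 35) / 12
  du <- param_value(ref_params, "du_bmi_unit")
  expect_equal(q_light - q_heavy, rep(du * 13.8 / 12, 12), tolerance = 1e-9)
  # all-alive cohort with utilities at most 1 accrues at most 1 QALY/year
  expect_lt(sum(q_light), 1)
  expect_gt(sum(q_light), 0.5)
})

test_that("dead occupancy accrues neither costs nor QALYs", {
  # immediate full mortality: only the surgery-cycle outlays are charged
  p <- ref_params
  for (nm in c("p_mortality_30d_gbp", "p_mortality_30d_sg",
               "p_mortality_30d_agb")) {
    p$parameters[[nm]]$value <- 1
    p$parameters[[nm]]$high <- 1
  }
  ctx <- model_context(p, ref_prof, arm = "surgery", horizon_months = 24)
  run <- simulate_arm(ctx)
  expect_equal(sum(run$occupancy[25, !ctx$space$states$alive]), 1)
  q <- accrue_qalys(run)
  expect_equal(sum(q[2:24]), 0)
  cost <- accrue_costs(run)
  expect_equal(sum(cost[2:24]), 0)
})

test_that("the dominance verdict table covers all nine sign combinations", {
  mk <- function(dc, dq) compute_cea(
    list(cost = 100 + dc, ly = 1, qaly = 1 + dq),
    list(cost = 100, ly = 1, qaly = 1), wtp = 35000)
  expect_equal(mk(-10, 0.5)$verdict, "dominant")
  expect_equal(mk(0, 0.5)$verdict, "dominant")   # weak (cost-neutral) dominance
  v <- mk(10, 0.5); expect_equal(v$verdict, "icer"); expect_equal(v$icer, 20)
  expect_equal(mk(10, -0.5)$verdict, "dominated")
  expect_equal(mk(0, -0.5)$verdict, "dominated")
  v2 <- mk(-10, -0.5); expect_equal(v2$verdict, "icer")
  expect_equal(v2$icer, 20)                      # south-west: savings per QALY lost
  expect_equal(mk(0, 0)$verdict, "equivalent")
  expect_equal(mk(10, 0)$verdict, "no_icer")
  expect_equal(mk(-10, 0)$verdict, "no_icer")
  # ICER only reported with matching nonzero signs
  expect_true(is.na(mk(-10, 0.5)$icer))
  expect_true(is.na(mk(10, 0)$icer))
  # net-benefit verdict at the threshold
  expect_true(mk(10, 0.5)$cost_effective_at_wtp)
  expect_false(mk(10, -0.5)$cost_effective_at_wtp)
})

test_that("with all treatment benefits removed, paying for surgery is dominated", {
  res <- run_comparison(benefit_free_params, horizon_months = 120)
  expect_gt(res$cea$d_cost, 0)       # tariff and visits still paid
  expect_lt(res$cea$d_qaly, 0)       # perioperative harm, no benefit
  expect_equal(res$cea$verdict, "dominated")
  # fully neutralised surgery (harms removed too): zero effect difference
  res0 <- run_comparison(null_effect_params, horizon_months = 120)
  expect_equal(res0$cea$d_qaly, 0, tolerance = 1e-12)
  expect_equal(res0$cea$verdict, "no_icer")
})

test_that("population extrapolation scales the per-patient increments", {
  inc <- list(d_cost = -8522, d_ly = 0.7, d_qaly = 3.2)
  ext <- population_extrapolation(inc, 5613)
  expect_equal(round(ext$person_years), 3929)
  expect_equal(round(ext$qalys), 17962)
  expect_equal(ext$total_savings, 8522 * 5613)
  ext0 <- population_extrapolation(inc, 0)
  expect_equal(unlist(ext0), c(total_savings = 0, person_years = 0, qalys = 0))
})
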