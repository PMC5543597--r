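test_that("identity matrices leave the occupancy unchanged", {
  sp <- toy_state_space(c("a", "b", "c"), c(TRUE, TRUE, FALSE))
  v0 <- c(0.5, 0.3, 0.2)
  tr <- run_cohort(sp, v0, 12, function(t) diag(3))
  expect_true(all(apply(tr$occupancy, 1, function(r) all(r == v0))))
})

test_that("two-state toy matches the geometric-survival closed form", {
  sp <- toy_state_space(c("alive", "dead"), c(TRUE, FALSE))
  M <- rbind(c(0.99, 0.01), c(0, 1))
  tr <- run_cohort(sp, c(1, 0), 12, function(t) M)
  expect_equal(tr$occupancy[13, 1], 0.99^12, tolerance = 1e-14)
  # undiscounted life years: closed-form sum of the survival series
  expect_equal(life_years(tr), sum(0.99^(1:12)) / 12, tolerance = 1e-14)
  # 12 fully-alive cycles give exactly one undiscounted life year
  tr_full <- run_cohort(sp, c(1, 0), 12, function(t) diag(2))
  expect_equal(life_years(tr_full), 1)
  # discounting can only shrink life years
  expect_lte(life_years(tr, discount_spec(0.03)), life_years(tr))
})

test_that("engine agrees with the matrix-power oracle on small chains", {
  # 4-state time-varying toy: two living, two absorbing
  set.seed(20)
  sp <- toy_state_space(c("s1", "s2", "d1", "d2"),
                        c(TRUE, TRUE, FALSE, FALSE))
  mats <- lapply(1:30, function(t) {
    p12 <- 0.05 + 0.001 * t; p1d <- 0.01; p2d <- 0.02 + 0.0005 * t
    rbind(c(1 - p12 - p1d, p12, p1d, 0),
          c(0.01, 1 - 0.01 - p2d - 0.003, p2d, 0.003),
          c(0, 0, 1, 0), c(0, 0, 0, 1))
  })
  tr <- run_cohort(sp, c(0.8, 0.2, 0, 0), 30, function(t) mats[[t]])
  oracle <- Reduce(`%*%`, mats, accumulate = TRUE)
  v0 <- c(0.8, 0.2, 0, 0)
  for (t in 1:30) {
    expect_lt(max(abs(tr$occupancy[t + 1, ] - as.vector(v0 %*% oracle[[t]]))),
              1e-12)
  }
})

test_that("run_cohort rejects bad inputs and non-stochastic matrices", {
  sp <- toy_state_space(c("a", "d"), c(TRUE, FALSE))
  expect_error(run_cohort(sp, c(0.4, 0.4), 5, function(t) diag(2)),
               "sum to 1")
  badM <- rbind(c(0.9, 0.2), c(0, 1))
  expect_error(run_cohort(sp, c(1, 0), 5, function(t)
    if (t < 3) diag(2) else badM), "cycle 3")
})

test_that("full-model fast path equals explicit matrix powering", {
  for (arm in c("surgery", "CMM")) {
    ctx <- model_context(ref_params, ref_prof, arm = arm,
                         horizon_months = 24)
    run <- simulate_arm(ctx)
    tr <- run_cohort(ctx$space, ctx$v0, 24,
                     function(t) build_transition_matrix(ctx, t))
    expect_lt(max(abs(run$occupancy - tr$occupancy)), 1e-12)
  }
})

test_that("transition rows are stochastic under random parameterisations", {
  set.seed(99)
  perturb <- function(params) {
    for (nm in c("rr_cvd_comorbidity", "rr_stroke_given_hf", "mort_rr_hf",
                 "mort_rr_stroke", "cf_mi", "cf_stroke",
                 "t2d_incidence_bmi25", "p_remission_year1",
                 "p_conversion_annual_agb")) {
      p <- params$parameters[[nm]]
      kind <- baricea:::.param_registry[[nm]]
      v <- if (kind == "probability") runif(1) else runif(1, 1, 4)
      params$parameters[[nm]]$value <- v
      params$parameters[[nm]]$low <- NULL
      params$parameters[[nm]]$high <- NULL
    }
    params
  }
  n_draws <- 50
  for (k in seq_len(n_draws)) {
    prm <- perturb(ref_params)
    prof <- cohort_profile(runif(1, 25, 60), runif(1), runif(1, 25, 60),
                           runif(1, 100, 200), runif(1), runif(1))
    ctx <- model_context(prm, prof, arm = sample(c("surgery", "CMM"), 1),
                         horizon_months = 24, space = small_space)
    M <- build_transition_matrix(ctx, sample(24, 1))
    expect_row_stochastic(M)
  }
  # and the full default space at a few random draws
  for (k in 1:3) {
    ctx <- model_context(perturb(ref_params), ref_prof, arm = "surgery",
                         horizon_months = 24)
    expect_row_stochastic(build_transition_matrix(ctx, sample(24, 1)))
  }
})

test_that("cohort mass is conserved and death is absorbing over a lifetime", {
  ctx <- model_context(ref_params, ref_prof, arm = "surgery")
  run <- simulate_arm(ctx)
  drift <- abs(rowSums(run$occupancy) - 1)
  expect_lt(max(drift), 1e-9)
  dead <- rowSums(run$occupancy[, !ctx$space$states$alive, drop = FALSE])
  expect_true(all(diff(dead) >= -1e-15))
  # by the closure age the whole cohort has died
  expect_gt(dead[nrow(run$occupancy)], 0.999)
})

test_that("surgery arm reduces 10-year diabetes incidence", {
  res <- run_comparison(ref_params, horizon_months = 120)
  t2d_s <- sum(res$surgery_run$flows$dm_inc)
  t2d_c <- sum(res$cmm_run$flows$dm_inc)
  expect_lt(t2d_s, t2d_c)
})
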