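test_that("one-way analysis spans the configured ranges and restores base", {
  p <- ref_params
  # collapse one parameter's range onto its value: zero swing expected
  p$parameters$cost_tia$low <- p$parameters$cost_tia$value
  p$parameters$cost_tia$high <- p$parameters$cost_tia$value
  dsa <- one_way_dsa(p, parameters = c("cost_tia", "cost_t2d_annual",
                                       "diabetes_prevalence"),
                     horizon_months = 120)
  expect_equal(dsa$swing[dsa$parameter == "cost_tia"], 0, tolerance = 1e-9)
  # binary diabetes evaluated at exactly 0 and 1 (recomputation oracle)
  row <- dsa[dsa$parameter == "diabetes_prevalence", ]
  expect_equal(row$low, 0); expect_equal(row$high, 1)
  p1 <- set_diab <- baricea:::set_param_value(
    baricea:::set_param_value(
      baricea:::set_param_value(p, "male_fraction", 1),
      "smoking_prevalence", 0), "diabetes_prevalence", 1)
  oracle_high <- baricea:::evaluate_model(p1, horizon_months = 120)$cea
  expect_equal(row$nmb_high, oracle_high$nmb, tolerance = 1e-9)
  # base case is invariant across entries (restoration regression)
  dsa2 <- one_way_dsa(p, parameters = c("cost_tia", "cost_t2d_annual"),
                      horizon_months = 120)
  expect_equal(attr(dsa, "base_nmb"), attr(dsa2, "base_nmb"),
               tolerance = 1e-12)
  expect_warning(one_way_dsa(p, parameters = c("cost_tia", "wtp_threshold"),
                             horizon_months = 120), "without a DSA range")
})

test_that("PSA with point-mass distributions reproduces the base case", {
  collapsed <- collapse_psa_dists(ref_params)
  psa <- run_psa(collapsed, n_iter = 3, seed = 7, horizon_months = 120)
  base <- baricea:::evaluate_model(ref_params, horizon_months = 120)$cea
  expect_identical(unique(psa$samples$d_cost), base$d_cost)
  expect_identical(unique(psa$samples$d_qaly), base$d_qaly)
})

test_that("PSA is seed-reproducible and draws match their distributions", {
  a <- run_psa(ref_params, n_iter = 4, seed = 31, horizon_months = 24)
  b <- run_psa(ref_params, n_iter = 4, seed = 31, horizon_months = 24)
  expect_identical(a$samples, b$samples)
  expect_identical(a$draws, b$draws)
  expect_equal(sum(unlist(a$summary)), 1)

  # marginal draw means within 3 SE of the point estimates, and tariffs
  # never drawn
  psa <- run_psa(ref_params, n_iter = 150, seed = 5, horizon_months = 12)
  expect_false("cost_agb" %in% colnames(psa$draws))
  for (nm in c("diabetes_prevalence", "male_fraction", "cost_t2d_annual")) {
    d <- ref_params$parameters[[nm]]$dist
    mu <- distribution_mean(d)
    sdv <- switch(d$family,
                  beta = sqrt(d$a * d$b / ((d$a + d$b)^2 * (d$a + d$b + 1))),
                  gamma = sqrt(d$a) * d$b)
    expect_lt(abs(mean(psa$draws[, nm]) - mu), 3 * sdv / sqrt(150) + 1e-12)
  }
  # classification definition on the recorded samples
  s <- psa$samples
  expect_true(all(s$class[s$d_cost < 0 & s$d_qaly > 0] == "cost_saving"))
})

test_that("cost-effectiveness plane bookkeeping is exact", {
  hand <- data.frame(d_qaly = c(1, -1, 1, -1), d_cost = c(5, 5, -5, -5))
  plane <- ce_plane_export(hand)
  expect_equal(unname(attr(plane, "quadrants")[c("NE", "NW", "SE", "SW")]),
               c(1, 1, 1, 1))
  strat <- ce_plane_export(hand, strata = factor(c("a", "a", "b", "b")))
  expect_equal(as.vector(table(strat$stratum)), c(2, 2))
})

test_that("acceptability curve is a direct count and monotone in WTP", {
  psa <- run_psa(ref_params, n_iter = 30, seed = 12, horizon_months = 60)
  grid <- seq(0, 80000, by = 10000)
  cc <- ceac(psa, grid)
  # brute-force recount at one threshold
  w <- 40000
  expect_equal(cc$prob_cost_effective[grid == w],
               mean(w * psa$samples$d_qaly - psa$samples$d_cost >= 0))
  # monotone non-decreasing when every iteration gains QALYs
  if (all(psa$samples$d_qaly > 0)) {
    expect_true(all(diff(cc$prob_cost_effective) >= 0))
  }
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
})
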