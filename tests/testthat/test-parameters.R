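test_that("reference parameter set reproduces the published inputs", {
  expect_equal(param_value(ref_params, "bmi_baseline"), 48.8)
  expect_equal(param_value(ref_params, "age_baseline"), 40.4)
  expect_equal(param_value(ref_params, "sbp_baseline"), 140.1)
  expect_equal(param_value(ref_params, "diabetes_prevalence"), 0.206)
  expect_equal(param_value(ref_params, "discount_rate"), 0.03)
  expect_equal(param_value(ref_params, "wtp_threshold"), 35000)
  expect_equal(param_value(ref_params, "cost_agb"), 5621)
  expect_equal(param_value(ref_params, "cost_gbp_sg"), 8104)
  # tariffs stay out of the PSA
  expect_true(ref_params$parameters$cost_agb$psa_excluded)
  expect_true(ref_params$parameters$cost_gbp_sg$psa_excluded)
  expect_false("cost_agb" %in% baricea:::psa_parameter_names(ref_params))
})

test_that("surgery mix shares are normalised and raw values preserved", {
  raw <- ref_params$metadata$surgery_mix_raw
  expect_equal(unname(raw), c(51, 17, 33))
  # oracle: direct normalisation by the raw total (101)
  expect_equal(unname(ref_params$surgery_mix),
               c(51, 17, 33) / 101, tolerance = 1e-12)
  expect_equal(sum(ref_params$surgery_mix), 1)
})

test_that("validation rejects out-of-range and incomplete inputs", {
  bad <- yaml::read_yaml(system.file("extdata", "reference_parameters.yaml",
                                     package = "baricea"))
  bad$parameters$diabetes_prevalence$value <- -0.1
  bad$parameters$diabetes_prevalence$low <- -0.1
  expect_error(load_parameter_set(bad), "outside \\[0, 1\\]")

  bad2 <- yaml::read_yaml(system.file("extdata", "reference_parameters.yaml",
                                      package = "baricea"))
  bad2$parameters$cost_t2d_annual <- NULL
  expect_error(load_parameter_set(bad2), "missing required parameter")

  bad3 <- yaml::read_yaml(system.file("extdata", "reference_parameters.yaml",
                                      package = "baricea"))
  bad3$parameters$age_baseline$value <- 90   # above its own DSA range
  expect_error(load_parameter_set(bad3), "outside DSA range")
})

test_that("serialisation round-trips every point estimate bit-exactly", {
  f <- tempfile(fileext = ".yaml")
  write_parameter_set(ref_params, f)
  back <- load_parameter_set(f)
  for (nm in names(ref_params$parameters)) {
    expect_identical(back$parameters[[nm]]$value,
                     ref_params$parameters[[nm]]$value)
  }
  tab <- export_parameter_table(ref_params)
  expect_setequal(tab$name, names(ref_params$parameters))
})

test_that("annual-to-cycle conversion satisfies the compounding identity", {
  expect_equal(annual_to_cycle_probability(0, 12), 0)
  expect_equal(annual_to_cycle_probability(1, 12), 1)
  # brute-force root-find oracle for p such that 1 - (1 - p)^12 = 0.12
  oracle <- uniroot(function(p) 1 - (1 - p)^12 - 0.12, c(0, 1),
                    tol = 1e-14)$root
  expect_equal(annual_to_cycle_probability(0.12, 12), oracle,
               tolerance = 1e-10)
  # property: strictly increasing, identity holds to 1e-12 relative error
  p <- seq(0.001, 0.999, length.out = 50)
  pc <- annual_to_cycle_probability(p, 12)
  expect_true(all(diff(pc) > 0))
  expect_lt(max(abs(cycle_to_annual_probability(pc, 12) - p) / p), 1e-12)
  expect_error(annual_to_cycle_probability(1.2, 12), "\\[0, 1\\]")
})

test_that("analytic distribution means match the published point estimates", {
  expect_equal(distribution_mean(distribution_spec("beta", 1030, 3970)), 0.206)
  expect_equal(distribution_mean(distribution_spec("gamma", 100, 38.67)), 3867)
  expect_equal(distribution_mean(distribution_spec("beta", 1, 1)), 0.5)
  expect_equal(distribution_mean(distribution_spec("normal", 40.4, 4.04)), 40.4)
  expect_equal(distribution_mean(distribution_spec("lognormal", 0, 0.5)),
               exp(0.125))
  expect_error(distribution_spec("beta", -1, 2), "positive")
  expect_error(distribution_spec("weibull", 1, 2))
})

test_that("distribution sampling is reproducible and respects support", {
  spec <- distribution_spec("beta", 1315, 3685)
  a <- sample_distribution(spec, 1000, seed = 42)
  b <- sample_distribution(spec, 1000, seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  g <- sample_distribution(distribution_spec("gamma", 0.34, 15982.32),
                           50000, seed = 7)
  expect_true(all(g >= 0))
  # sample mean within 3 SE of the analytic gamma mean (shape x scale)
  se <- sqrt(0.34) * 15982.32 / sqrt(50000)
  expect_lt(abs(mean(g) - 0.34 * 15982.32), 3 * se)
})

test_that("distribution means sit close to point estimates across the set", {
  chk <- check_distribution_consistency(ref_params)
  # every reference row is within the 5% flag rule
  expect_false(any(chk$flagged))
  # the known near-misses are present but small (heart-failure cost, SBP)
  hf <- chk[chk$name == "cost_hf_annual", ]
  expect_lt(hf$rel_diff, 0.05)
  expect_gt(hf$dist_mean, 5400)  # gamma mean 0.34 * 15982.32 = 5434, not 5393
})
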