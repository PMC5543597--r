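# Shared fixtures: built once per test run.

ref_params <- reference_parameters()
ref_prof <- reference_profile(ref_params)

# a parameter set with every treatment effect of surgery switched off
# (same weight/SBP/diabetes dynamics in both arms, no perioperative harm)
null_effect_params <- local({
  p <- ref_params
  for (nm in c("bmi_loss_12m_gbp", "bmi_loss_12m_sg", "bmi_loss_12m_agb",
               "p_remission_year1", "p_remission_later",
               "p_mortality_30d_gbp", "p_mortality_30d_sg",
               "p_mortality_30d_agb", "p_sae_gbp", "p_sae_sg", "p_sae_agb",
               "p_complication_gbp", "p_complication_sg",
               "p_complication_agb", "p_conversion_annual_agb")) {
    p$parameters[[nm]]$value <- 0
  }
  p$parameters$sbp_delta_surgery_nondiabetic$value <- 0
  p$parameters$sbp_delta_surgery_diabetic$value <- 0
  for (nm in names(p$parameters)) {   # keep ranges consistent with 0 values
    lo <- p$parameters[[nm]]$low
    if (!is.null(lo) && p$parameters[[nm]]$value < lo) {
      p$parameters[[nm]]$low <- p$parameters[[nm]]$value
    }
  }
  p
})

# replace every PSA distribution by a numerically degenerate normal at the
# point estimate (draws reproduce the value bit-exactly)
collapse_psa_dists <- function(params) {
  for (nm in names(params$parameters)) {
    p <- params$parameters[[nm]]
    if (!is.null(p$dist) && !p$psa_excluded) {
      params$parameters[[nm]]$dist <-
        distribution_spec("normal", p$value, 1e-300)
    }
  }
  params
}

# benefits removed but perioperative harms kept: surgery can only lose
benefit_free_params <- local({
  p <- ref_params
  for (nm in c("bmi_loss_12m_gbp", "bmi_loss_12m_sg", "bmi_loss_12m_agb",
               "p_remission_year1", "p_remission_later")) {
    p$parameters[[nm]]$value <- 0
    lo <- p$parameters[[nm]]$low
    if (!is.null(lo) && lo > 0) p$parameters[[nm]]$low <- 0
  }
  p$parameters$sbp_delta_surgery_nondiabetic$value <- 0
  p$parameters$sbp_delta_surgery_diabetic$value <- 0
  p
})

# small state space for matrix-heavy property tests
small_space <- build_state_space(state_space_config(
  conditions = c("mi", "hf"), diabetes = TRUE, conversion = TRUE,
  cvd_cap = 2L))

expect_row_stochastic <- function(M, tol = 1e-10) {
  expect_true(all(M >= -1e-12))
  expect_lt(max(abs(rowSums(M) - 1)), tol)
}
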