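# Placeholder risk equations.
#
# The cardiovascular risk of a modelled cohort depends on age, sex,
# systolic blood pressure, BMI category, diabetes and smoking, through a
# Framingham-style logistic model on the annual probability scale:
#
#   logit(p_annual) = intercept + b_age (age - 40) + b_male male
#                     + b_sbp (SBP - 120) + b_bmi bmi_score
#                     + b_diab diabetic + b_smoke smoker
#
# The true coefficients live in external literature and are not shipped;
# the defaults below are documented synthetic placeholders whose
# intercepts are solved so that the reference cohort's annual risks match
# order-of-magnitude 10-year calibration targets (the slope coefficients
# are fixed, literature-plausible values). They are swappable via the
# arguments of default_risk_coefficients().

.cvd_events <- c("angina", "mi", "stroke", "hf", "pad", "tia")
.cvd_conditions <- c("angina", "mi", "stroke", "hf", "pad")

#' Cohort baseline profile
#'
#' @param age baseline age in years (18-100).
#' @param male male fraction (0-1; 0/1 for single-sex cohorts).
#' @param bmi baseline body mass index, kg/m^2 (20-80).
#' @param sbp baseline systolic blood pressure, mmHg (90-250).
#' @param diabetic baseline type 2 diabetes fraction (0-1).
#' @param smoker smoking fraction (0-1).
#' @return an object of class `baricea_profile`.
#' @export
cohort_profile <- function(age, male, bmi, sbp, diabetic, smoker) {
  stopifnot(age >= 18, age <= 100, bmi >= 20, bmi <= 80,
            sbp >= 90, sbp <= 250,
            male >= 0, male <= 1, diabetic >= 0, diabetic <= 1,
            smoker >= 0, smoker <= 1)
  structure(list(age = age, male = male, bmi = bmi, sbp = sbp,
                 diabetic = diabetic, smoker = smoker),
            class = "baricea_profile")
}

#' Reference cohort profile implied by a parameter set
#' @param params a `baricea_parameter_set`.
#' @return a [cohort_profile()] built from the baseline-characteristic
#'   parameters.
#' @export
reference_profile <- function(params = reference_parameters()) {
  cohort_profile(
    age = param_value(params, "age_baseline"),
    male = param_value(params, "male_fraction"),
    bmi = param_value(params, "bmi_baseline"),
    sbp = param_value(params, "sbp_baseline"),
    diabetic = param_value(params, "diabetes_prevalence"),
    smoker = param_value(params, "smoking_prevalence")
  )
}

# internal: BMI score entering the linear predictor.
# "continuous" (default): per-unit excess over the 25 kg/m^2 reference;
# "category": WHO-style classes scored by their midpoint excess.
bmi_score <- function(bmi, mode = c("continuous", "category")) {
  mode <- match.arg(mode)
  if (mode == "continuous") return(pmax(bmi - 25, 0))
  mids <- c(22.5, 27.5, 32.5, 37.5, 45)
  idx <- findInterval(bmi, c(25, 30, 35, 40)) + 1L
  pmax(mids[idx] - 25, 0)
}

#' Default (placeholder) risk-equation coefficients
#'
#' Builds the packaged synthetic risk coefficients: logistic slope
#' coefficients per event, intercepts solved so that the annual event
#' probabilities of `calibration_profile` equal
#' `1 - (1 - target_10y)^(1/10)` (the static-cohort equivalent of the
#' 10-year calibration targets), plus comorbidity relative risks,
#' chronic-condition mortality multipliers, acute case fatality, and the
#' log-linear BMI model for diabetes incidence, all taken from `params`.
#'
#' @param params a `baricea_parameter_set` supplying the comorbidity /
#'   fatality / diabetes-incidence values.
#' @param bmi_entry how BMI enters CVD risk: `"continuous"` (per kg/m^2
#'   above 25, default) or `"category"` (WHO classes scored by midpoint).
#'   The continuous default preserves the monotone gain of surgery in
#'   baseline BMI across cohorts whose BMI falls within one WHO class.
#' @param calibration_profile profile at which intercepts are solved
#'   (default: the reference cohort of `params`).
#' @param target_10y named vector of 10-year cumulative-risk calibration
#'   targets per event.
#' @param slopes named list of slope-coefficient vectors per event
#'   (elements `age`, `male`, `sbp`, `bmi`, `diab`, `smoke`); defaults are
#'   the packaged placeholders.
#' @return an object of class `baricea_risk_coefficients`.
#' @export
default_risk_coefficients <- function(params = reference_parameters(),
                                      bmi_entry = c("continuous", "category"),
                                      calibration_profile = NULL,
                                      target_10y = c(angina = 0.03, mi = 0.06,
                                                     stroke = 0.03, hf = 0.03,
                                                     pad = 0.03, tia = 0.005),
                                      slopes = NULL) {
  bmi_entry <- match.arg(bmi_entry)
  prof <- calibration_profile %||% reference_profile(params)
  stopifnot(all(.cvd_events %in% names(target_10y)))

  default_slopes <- list(
    #          age   male  sbp    bmi   diab  smoke
    angina = c(0.05, 0.30, 0.015, 0.02, 0.50, 0.30),
    mi     = c(0.05, 0.50, 0.015, 0.02, 0.69, 0.60),
    stroke = c(0.05, 0.20, 0.030, 0.02, 0.69, 0.40),
    hf     = c(0.05, 0.30, 0.020, 0.03, 0.50, 0.30),
    pad    = c(0.05, 0.40, 0.015, 0.02, 0.69, 0.70),
    tia    = c(0.05, 0.20, 0.030, 0.02, 0.50, 0.40)
  )
  slopes <- slopes %||% default_slopes
  coef_mat <- do.call(rbind, slopes[.cvd_events])
  colnames(coef_mat) <- c("age", "male", "sbp", "bmi", "diab", "smoke")

  p_ann_target <- 1 - (1 - target_10y[.cvd_events])^(1 / 10)
  lp_ref <- coef_mat %*% c(prof$age - 40, prof$male, prof$sbp - 120,
                           bmi_score(prof$bmi, bmi_entry), prof$diabetic,
                           prof$smoker)
  intercepts <- stats::qlogis(p_ann_target) - as.vector(lp_ref)
  names(intercepts) <- .cvd_events

  structure(list(
    events = .cvd_events,
    conditions = .cvd_conditions,
    intercepts = intercepts,
    coefficients = coef_mat,
    bmi_entry = bmi_entry,
    comorbidity_rr = list(
      generic = param_value(params, "rr_cvd_comorbidity"),
      hf_stroke = param_value(params, "rr_stroke_given_hf")
    ),
    case_fatality = c(angina = 0, mi = param_value(params, "cf_mi"),
                      stroke = param_value(params, "cf_stroke"),
                      hf = 0, pad = 0, tia = 0),
    mortality_rr = c(
      t2d = param_value(params, "mort_rr_t2d"),
      angina = param_value(params, "mort_rr_angina"),
      mi = param_value(params, "mort_rr_mi"),
      stroke = param_value(params, "mort_rr_stroke"),
      hf = param_value(params, "mort_rr_hf"),
      pad = param_value(params, "mort_rr_pad")
    ),
    t2d = list(
      incidence_bmi25 = param_value(params, "t2d_incidence_bmi25"),
      rr_per_bmi_unit = param_value(params, "t2d_rr_per_bmi_unit")
    )
  ), class = "baricea_risk_coefficients")
}

# internal: comorbidity relative risk of `target` given one existing
# `condition`
comorbidity_rr <- function(coeffs, condition, target) {
  if (!condition %in% coeffs$conditions) stop("unknown condition: ", condition)
  if (!target %in% coeffs$events) stop("unknown event: ", target)
  if (condition == "hf" && target == "stroke") {
    coeffs$comorbidity_rr$hf_stroke
  } else {
    coeffs$comorbidity_rr$generic
  }
}

# internal: annual baseline probability of each CVD event for given
# covariates (vectorised over events); no comorbidity amplification
base_event_probability_annual <- function(coeffs, age, male, sbp, bmi,
                                          diabetic, smoker) {
  lp <- coeffs$intercepts + as.vector(
    coeffs$coefficients %*% c(age - 40, male, sbp - 120,
                              bmi_score(bmi, coeffs$bmi_entry),
                              diabetic, smoker))
  stats::plogis(lp)
}

#' Per-cycle probability of a cardiovascular event
#'
#' Evaluates the logistic risk equation at the given profile, multiplies
#' by the comorbidity relative risks of every condition in `existing`,
#' clips the annual probability to `[0, 1]`, and converts to a monthly
#' probability (or returns the annual value with `per = "year"`).
#'
#' @param event one of `"angina"`, `"mi"`, `"stroke"`, `"hf"`, `"pad"`,
#'   `"tia"`.
#' @param profile_at_t a [cohort_profile()] describing the risk factors at
#'   the evaluation time.
#' @param existing character vector of established conditions (subset of
#'   `"angina"`, `"mi"`, `"stroke"`, `"hf"`, `"pad"`).
#' @param coeffs a [default_risk_coefficients()] object.
#' @param per `"month"` (default) or `"year"`.
#' @return event probability per cycle (or per year).
#' @export
event_probability <- function(event, profile_at_t, existing = character(0),
                              coeffs = default_risk_coefficients(),
                              per = c("month", "year")) {
  per <- match.arg(per)
  if (!event %in% coeffs$events) stop("unknown event: ", event)
  p <- profile_at_t
  ann <- base_event_probability_annual(
    coeffs, p$age, p$male, p$sbp, p$bmi, p$diabetic, p$smoker
  )[match(event, coeffs$events)]
  for (cond in existing) ann <- ann * comorbidity_rr(coeffs, cond, event)
  ann <- clip01(ann)
  if (per == "year") ann else annual_to_cycle_probability(ann, 12L)
}

#' Annual type 2 diabetes incidence as a function of BMI
#'
#' Log-linear in BMI above the 25 kg/m^2 reference:
#' `incidence_bmi25 * rr_per_bmi_unit^(bmi - 25)`, clipped to `[0, 1]`.
#'
#' @param bmi body mass index, kg/m^2 (vectorised).
#' @param coeffs a [default_risk_coefficients()] object.
#' @return annual incidence probability.
#' @export
t2d_incidence_annual <- function(bmi, coeffs = default_risk_coefficients()) {
  clip01(coeffs$t2d$incidence_bmi25 *
           coeffs$t2d$rr_per_bmi_unit^pmax(bmi - 25, 0))
}

#' Generate an individual-level cohort fixture
#'
#' Samples `n` individual baselines from the baseline-characteristic
#' distributions of the parameter set (normal age and BMI, gamma SBP,
#' Bernoulli sex/diabetes/smoking), truncated to the profile bounds of
#' [cohort_profile()]. With the default profile the sample means
#' reproduce the reference point estimates. Reproducible by seed.
#'
#' @param profile optional [cohort_profile()] overriding the distribution
#'   centres (defaults to the reference profile of `params`).
#' @param n number of individuals (`n >= 1`).
#' @param seed integer seed.
#' @param params a `baricea_parameter_set`.
#' @return data frame with one row per individual: `age`, `male`, `bmi`,
#'   `sbp`, `diabetic`, `smoker`.
#' @export
generate_cohort_fixture <- function(profile = NULL, n, seed = 1L,
                                    params = reference_parameters()) {
  stopifnot(n >= 1)
  prof <- profile %||% reference_profile(params)
  set.seed(as.integer(seed))
  n <- as.integer(n)
  rtrunc <- function(draw, lo, hi) {
    x <- draw(n)
    for (k in 1:100) {
      bad <- which(x < lo | x > hi)
      if (!length(bad)) break
      x[bad] <- draw(length(bad))
    }
    pmin(hi, pmax(lo, x))
  }
  sbp_shape <- 55.53  # shape of the reference SBP gamma; scale from mean
  data.frame(
    age = rtrunc(function(m) stats::rnorm(m, prof$age, 4.04), 18, 100),
    male = stats::rbinom(n, 1, prof$male),
    bmi = rtrunc(function(m) stats::rnorm(m, prof$bmi, 6.5), 20, 80),
    sbp = rtrunc(function(m) stats::rgamma(m, shape = sbp_shape,
                                           scale = prof$sbp / sbp_shape),
                 90, 250),
    diabetic = stats::rbinom(n, 1, prof$diabetic),
    smoker = stats::rbinom(n, 1, prof$smoker)
  )
}
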