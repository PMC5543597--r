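# Risk-factor trajectories.
#
# Surgery reduces BMI linearly from baseline to the procedure-specific
# 12-month level; beyond the last observation the loss is partially
# regained along piecewise-linear anchors (fraction of the 12-month loss
# retained at years 2, 10 and 15), and after 15 years the BMI level is
# permanent until death. The comparator arm follows a slow configured
# drift. SBP moves by a configured 12-month delta (different for diabetic
# and non-diabetic strata) and is constant thereafter.

.procedures <- c("GBP", "SG", "AGB", "mix")

# internal: 12-month fractional BMI loss for a procedure (mix-weighted)
procedure_bmi_loss <- function(procedure, params) {
  losses <- c(GBP = param_value(params, "bmi_loss_12m_gbp"),
              SG = param_value(params, "bmi_loss_12m_sg"),
              AGB = param_value(params, "bmi_loss_12m_agb"))
  if (procedure == "mix") sum(params$surgery_mix * losses[names(params$surgery_mix)])
  else losses[[procedure]]
}

# internal: fraction of the 12-month loss retained m months post-surgery
retained_fraction <- function(m, params) {
  anchors_y <- c(1, 2, 10, 15)
  anchors_r <- c(1,
                 param_value(params, "bmi_retained_year2"),
                 param_value(params, "bmi_retained_year10"),
                 param_value(params, "bmi_retained_year15"))
  y <- m / 12
  out <- numeric(length(m))
  out[m <= 12] <- (m[m <= 12] / 12)            # linear descent to the nadir
  mid <- m > 12 & y < 15
  out[mid] <- stats::approx(anchors_y, anchors_r, xout = y[mid],
                            rule = 2)$y
  out[y >= 15] <- anchors_r[4]                 # 15-year plateau
  out
}

#' BMI trajectory of a cohort
#'
#' @param profile a [cohort_profile()].
#' @param arm `"surgery"` or `"CMM"` (conventional medical management).
#' @param procedure `"GBP"`, `"SG"`, `"AGB"`, or `"mix"` (share-weighted
#'   across the surgery mix of `params`).
#' @param horizon_months number of monthly cycles (`>= 1`).
#' @param params a `baricea_parameter_set`.
#' @param surgery_month cycle in which surgery takes place (1 = immediate;
#'   larger values model delayed surgery, with the cohort following the
#'   comparator drift until then and the loss applied to the
#'   then-current BMI).
#' @return object of class `baricea_trajectory`: list with `values`
#'   (length `horizon_months + 1`, entry `t + 1` giving the value at
#'   cycle `t`), `arm`, `procedure`, `measure = "bmi"`.
#' @export
bmi_trajectory <- function(profile, arm = c("surgery", "CMM"),
                           procedure = "mix", horizon_months,
                           params = reference_parameters(),
                           surgery_month = 1L) {
  arm <- match.arg(arm)
  procedure <- match.arg(procedure, .procedures)
  stopifnot(horizon_months >= 1)
  t <- 0:horizon_months
  drift <- param_value(params, "cmm_bmi_drift_annual")
  cmm <- profile$bmi + drift * t / 12
  values <- cmm
  if (arm == "surgery") {
    s0 <- as.integer(surgery_month)
    post <- t >= s0
    b_start <- profile$bmi + drift * (s0 - 1) / 12
    loss12 <- b_start * procedure_bmi_loss(procedure, params)
    m <- t[post] - s0 + 1
    values[post] <- b_start - loss12 * retained_fraction(m, params)
  }
  structure(list(values = pmin(80, pmax(20, values)), arm = arm,
                 procedure = procedure, measure = "bmi",
                 surgery_month = if (arm == "surgery") surgery_month else NA),
            class = "baricea_trajectory")
}

#' SBP trajectory of a cohort
#'
#' @inheritParams bmi_trajectory
#' @param diabetic logical; selects the diabetic or non-diabetic
#'   post-surgery SBP delta.
#' @return a `baricea_trajectory` with `measure = "sbp"`.
#' @export
sbp_trajectory <- function(profile, arm = c("surgery", "CMM"),
                           diabetic = FALSE, horizon_months,
                           params = reference_parameters(),
                           surgery_month = 1L) {
  arm <- match.arg(arm)
  stopifnot(horizon_months >= 1)
  t <- 0:horizon_months
  drift <- param_value(params, "sbp_delta_cmm_annual")
  values <- profile$sbp + drift * t / 12
  if (arm == "surgery") {
    s0 <- as.integer(surgery_month)
    delta <- if (isTRUE(diabetic)) {
      param_value(params, "sbp_delta_surgery_diabetic")
    } else {
      param_value(params, "sbp_delta_surgery_nondiabetic")
    }
    post <- t >= s0
    m <- t[post] - s0 + 1
    values[post] <- (profile$sbp + drift * (s0 - 1) / 12) +
      delta * pmin(m / 12, 1)
  }
  structure(list(values = pmin(250, pmax(90, values)), arm = arm,
                 procedure = NA, measure = "sbp",
                 surgery_month = if (arm == "surgery") surgery_month else NA),
            class = "baricea_trajectory")
}

#' Extract the value of a trajectory at a cycle
#' @param traj a `baricea_trajectory`.
#' @param t cycle index (0 = baseline), vectorised.
#' @return numeric values.
#' @export
trajectory_at <- function(traj, t) traj$values[t + 1L]

#' Export trajectories as a delimited table
#'
#' @param ... named `baricea_trajectory` objects (e.g. `bmi =`, `sbp =`).
#' @param path optional TSV path.
#' @return data frame with columns `cycle`, `arm`, then one column per
#'   trajectory.
#' @export
export_trajectory <- function(..., path = NULL) {
  trajs <- list(...)
  stopifnot(length(trajs) >= 1)
  n <- length(trajs[[1]]$values)
  df <- data.frame(cycle = 0:(n - 1), arm = trajs[[1]]$arm)
  for (nm in names(trajs)) df[[nm]] <- trajs[[nm]]$values
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Monthly probability of type 2 diabetes remission after surgery
#'
#' Configured step schedule: a high annual remission probability during
#' the first post-operative year, a lower one thereafter; zero in the
#' comparator arm, where remission is not modelled.
#'
#' @param months_since_surgery months elapsed since the operation
#'   (`>= 0`; 0 means the surgery cycle itself, before any remission).
#' @param params a `baricea_parameter_set`.
#' @param arm `"surgery"` or `"CMM"`.
#' @return monthly remission probability.
#' @export
t2d_remission_probability <- function(months_since_surgery,
                                      params = reference_parameters(),
                                      arm = c("surgery", "CMM")) {
  arm <- match.arg(arm)
  m <- months_since_surgery
  if (any(m < 0)) stop("months_since_surgery must be >= 0")
  if (arm == "CMM") return(rep(0, length(m)))
  annual <- ifelse(m >= 1 & m <= 12,
                   param_value(params, "p_remission_year1"),
                   param_value(params, "p_remission_later"))
  annual[m < 1] <- 0
  annual_to_cycle_probability(annual, 12L)
}

#' Perioperative and conversion-surgery outcome probabilities
#'
#' @param procedure `"GBP"`, `"SG"`, `"AGB"`, or `"mix"` (share-weighted).
#' @param params a `baricea_parameter_set`.
#' @return list with `thirty_day_mortality`, `severe_adverse_event`,
#'   `complication` (probabilities applied in the surgery cycle) and
#'   `annual_conversion` (adjustable-banding conversion rate; zero for the
#'   other procedures, share-weighted for `"mix"`).
#' @export
surgical_cycle_outcomes <- function(procedure = "mix",
                                    params = reference_parameters()) {
  procedure <- match.arg(procedure, .procedures)
  per_proc <- function(stub) c(
    GBP = param_value(params, paste0(stub, "_gbp")),
    SG = param_value(params, paste0(stub, "_sg")),
    AGB = param_value(params, paste0(stub, "_agb"))
  )
  conv <- c(GBP = 0, SG = 0,
            AGB = param_value(params, "p_conversion_annual_agb"))
  pick <- function(v) {
    if (procedure == "mix") sum(params$surgery_mix * v[names(params$surgery_mix)])
    else unname(v[[procedure]])
  }
  list(
    thirty_day_mortality = pick(per_proc("p_mortality_30d")),
    severe_adverse_event = pick(per_proc("p_sae")),
    complication = pick(per_proc("p_complication")),
    annual_conversion = pick(conv)
  )
}
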