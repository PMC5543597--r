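# Cost and utility accrual over occupancy traces, discounting, and
# incremental cost-effectiveness.

#' Discounting specification
#'
#' Annual rate with costs and outcomes beyond the first year discounted;
#' under the default `"annual_step"` convention cycles 1-12 are
#' undiscounted and cycle `t > 12` carries the factor
#' `(1 + rate)^(-floor((t - 1) / 12))`, i.e. annual steps starting at
#' month 13. `"monthly"` applies smooth monthly compounding
#' `(1 + rate)^(-(t - 1) / 12)` instead.
#'
#' @param rate annual discount rate (`>= 0`; default 3%).
#' @param convention `"annual_step"` (default) or `"monthly"`.
#' @return an object of class `baricea_discount`.
#' @export
discount_spec <- function(rate = 0.03,
                          convention = c("annual_step", "monthly")) {
  if (!is.numeric(rate) || rate < 0) stop("discount rate must be >= 0")
  structure(list(rate = rate, convention = match.arg(convention)),
            class = "baricea_discount")
}

# internal: per-cycle discount factors for cycles 1..H
discount_factors <- function(H, spec) {
  t <- seq_len(H)
  if (spec$convention == "monthly") {
    (1 + spec$rate)^(-(t - 1) / 12)
  } else {
    ifelse(t <= 12, 1, (1 + spec$rate)^(-floor((t - 1) / 12)))
  }
}

#' Discount a per-cycle series and return its total
#'
#' @param series numeric vector, entry `t` holding the amount accrued in
#'   cycle `t` (months).
#' @param spec a [discount_spec()].
#' @return the discounted sum.
#' @export
discount_series <- function(series, spec = discount_spec()) {
  stopifnot(inherits(spec, "baricea_discount"), all(is.finite(series)))
  sum(series * discount_factors(length(series), spec))
}

# internal: mix-weighted procedure tariff
procedure_tariff <- function(procedure, params) {
  tar <- c(GBP = param_value(params, "cost_gbp_sg"),
           SG = param_value(params, "cost_gbp_sg"),
           AGB = param_value(params, "cost_agb"))
  if (procedure == "mix") sum(params$surgery_mix * tar[names(params$surgery_mix)])
  else tar[[procedure]]
}

# internal: annual cost attached to each living state (euros/year)
state_cost_vector <- function(ctx, params = ctx$params) {
  st <- ctx$space$states
  living <- ctx$edges$living
  tun <- ctx$space$tunnel_months
  cv <- numeric(ctx$nL)
  cv <- cv + ifelse(st$dm[living] == "T2D",
                    param_value(params, "cost_t2d_annual"), 0)
  ph <- st$st_phase[living]
  cv <- cv + ifelse(ph >= 1 & ph <= tun / 2,
                    param_value(params, "cost_poststroke_year1"),
                    ifelse(ph > tun / 2,
                           param_value(params, "cost_poststroke_year2"), 0))
  cm <- ctx$cond_mat
  cv <- cv + cm[, "angina"] * param_value(params, "cost_angina_annual")
  cv <- cv + cm[, "mi"] * param_value(params, "cost_post_mi_annual")
  cv <- cv + cm[, "hf"] * param_value(params, "cost_hf_annual")
  cv <- cv + cm[, "pad"] * param_value(params, "cost_pad_annual")
  cv <- cv + (st$track[living] == "COMP") *
    param_value(params, "cost_complication_annual")
  cv
}

#' Accrue per-cycle costs over a cohort run
#'
#' Combines annual state costs (charged as occupancy x annual cost / 12),
#' one-time event costs on the event flows (acute myocardial infarction
#' and stroke, transient ischemic attack, severe perioperative adverse
#' events, conversion surgery), the procedure tariff at the surgery
#' cycle, and the published follow-up visit schedule (pre-operative
#' surgeon/dietician/psychologist consultations, first-month surgeon and
#' nurse visits, a surgeon visit at one year, an annual dietician
#' consultation from year two; an annual GP plus dietician visit in the
#' comparator track).
#'
#' @param run a [simulate_arm()] result.
#' @param params parameter set (defaults to the run's).
#' @return numeric vector of length `horizon`: undiscounted euros accrued
#'   per cycle.
#' @export
accrue_costs <- function(run, params = run$ctx$params) {
  ctx <- run$ctx
  H <- ctx$horizon
  occ <- run$occupancy
  living <- ctx$edges$living
  f <- run$flows

  cv <- state_cost_vector(ctx, params) / 12
  cost <- as.vector(occ[1L + seq_len(H), living, drop = FALSE] %*% cv)

  ev <- f$ev_nf + f$ev_f
  cost <- cost +
    ev[, "mi"] * param_value(params, "cost_mi_acute") +
    ev[, "stroke"] * param_value(params, "cost_stroke_acute") +
    f$tia * param_value(params, "cost_tia") +
    f$conversion * param_value(params, "cost_conversion") +
    f$surgery * procedure_tariff(ctx$procedure, params) +
    f$sae * param_value(params, "cost_sae_event")

  st <- ctx$space$states
  surg_tracks <- st$track[living] %in% c("SURG", "COMP", "CONV")
  cmm_track <- st$track[living] == "CMM"
  occ_l <- occ[1L + seq_len(H), living, drop = FALSE]
  surg_occ <- rowSums(occ_l[, surg_tracks, drop = FALSE])
  cmm_occ <- rowSums(occ_l[, cmm_track, drop = FALSE])

  c_surgeon <- param_value(params, "cost_visit_surgeon")
  c_diet <- param_value(params, "cost_visit_dietician")
  c_psych <- param_value(params, "cost_visit_psychologist")
  c_nurse <- param_value(params, "cost_visit_nurse")
  c_gp <- param_value(params, "cost_visit_gp")

  if (is.finite(ctx$s0) && ctx$s0 <= H) {
    s0 <- ctx$s0
    # pre-operative work-up, charged on the operated flow
    cost[s0] <- cost[s0] + f$surgery[s0] * (2 * c_surgeon + c_diet + c_psych)
    if (s0 + 1 <= H) {
      cost[s0 + 1] <- cost[s0 + 1] + surg_occ[s0 + 1] * (2 * c_surgeon + c_nurse)
    }
    if (s0 + 12 <= H) cost[s0 + 12] <- cost[s0 + 12] + surg_occ[s0 + 12] * c_surgeon
    if (s0 + 24 <= H) {
      ann <- seq(s0 + 24, H, by = 12)
      cost[ann] <- cost[ann] + surg_occ[ann] * c_diet
    }
  }
  ann_cmm <- seq(12, H, by = 12)
  if (length(ann_cmm)) {
    cost[ann_cmm] <- cost[ann_cmm] + cmm_occ[ann_cmm] * (c_gp + c_diet)
  }
  cost
}

#' Accrue per-cycle quality-adjusted life years over a cohort run
#'
#' Utility composition is additive with a floor at zero: an age-declining
#' baseline, a per-unit decrement for BMI above 25 kg/m^2 (evaluated on
#' the trajectory of each state's track), a diabetes decrement (lifted in
#' remission), per-condition cardiovascular decrements, a decrement for
#' the chronic surgical-complication state, and a one-month transient
#' decrement per TIA event. Dead states contribute zero.
#'
#' @inheritParams accrue_costs
#' @return numeric vector of length `horizon`: undiscounted QALYs accrued
#'   per cycle.
#' @export
accrue_qalys <- function(run, params = run$ctx$params) {
  ctx <- run$ctx
  H <- ctx$horizon
  living <- ctx$edges$living
  st <- ctx$space$states
  occ_l <- run$occupancy[1L + seq_len(H), living, drop = FALSE]

  dec <- numeric(ctx$nL)
  dec <- dec + (st$dm[living] == "T2D") * param_value(params, "du_t2d")
  cm <- ctx$cond_mat
  dec <- dec + cm[, "angina"] * param_value(params, "du_angina") +
    cm[, "mi"] * param_value(params, "du_post_mi") +
    cm[, "stroke"] * param_value(params, "du_stroke") +
    cm[, "hf"] * param_value(params, "du_hf") +
    cm[, "pad"] * param_value(params, "du_pad") +
    (st$track[living] == "COMP") * param_value(params, "du_complication")

  u20 <- param_value(params, "utility_age20")
  uslope <- param_value(params, "utility_age_slope")
  du_bmi <- param_value(params, "du_bmi_unit")
  du_tia <- param_value(params, "du_tia")

  q <- numeric(H)
  for (t in seq_len(H)) {
    age <- ctx$age0 + (t - 1) / 12
    base <- clip01(u20 - uslope * max(age - 20, 0))
    u <- base - du_bmi * pmax(ctx$bmi[ctx$grp, t + 1L] - 25, 0) - dec
    u <- pmax(u, 0)
    q[t] <- sum(occ_l[t, ] * u) / 12 - run$flows$tia[t] * du_tia / 12
  }
  q
}

#' Summarise one arm: discounted cost, life years and QALYs
#'
#' @param run a [simulate_arm()] result.
#' @param discount a [discount_spec()]; defaults to the run's configured
#'   annual rate.
#' @param horizon optional truncation in cycles (e.g. 120 for a 10-year
#'   view of a lifetime run).
#' @return list with `cost`, `ly`, `qaly` (discounted) and their
#'   undiscounted counterparts.
#' @export
arm_summary <- function(run, discount = NULL, horizon = NULL) {
  params <- run$ctx$params
  discount <- discount %||% discount_spec(param_value(params, "discount_rate"))
  H <- run$ctx$horizon
  keep <- seq_len(if (is.null(horizon)) H else min(H, as.integer(horizon)))
  cost <- accrue_costs(run)[keep]
  qaly <- accrue_qalys(run)[keep]
  ly <- rowSums(run$occupancy[1L + keep,
                              run$ctx$edges$living, drop = FALSE]) / 12
  nodisc <- discount_spec(0)
  list(cost = discount_series(cost, discount),
       ly = discount_series(ly, discount),
       qaly = discount_series(qaly, discount),
       cost_undiscounted = discount_series(cost, nodisc),
       ly_undiscounted = discount_series(ly, nodisc),
       qaly_undiscounted = discount_series(qaly, nodisc))
}

#' Incremental cost-effectiveness of surgery versus comparator
#'
#' Increments are surgery minus comparator. The verdict follows the
#' standard dominance table (weak dominance on the zero-cost boundary):
#'
#' | sign ΔQALY | sign ΔC | verdict |
#' |---|---|---|
#' | + | - or 0 | `dominant` |
#' | + | + | `icer` (ΔC/ΔQALY) |
#' | - | + or 0 | `dominated` |
#' | - | - | `icer` (south-west: savings per QALY forgone) |
#' | 0 | 0 | `equivalent` |
#' | 0 | + or - | `no_icer` (zero effect difference) |
#'
#' An ICER is reported only when ΔC and ΔQALY share a nonzero sign.
#' Cost-effectiveness at the willingness-to-pay threshold is judged by
#' the incremental net monetary benefit `wtp * ΔQALY - ΔC >= 0`.
#'
#' @param surgery,cmm per-arm results: lists with `cost`, `ly`, `qaly`.
#' @param wtp willingness-to-pay threshold, euros/QALY.
#' @return an object of class `baricea_cea`.
#' @export
compute_cea <- function(surgery, cmm, wtp = 35000) {
  need <- c("cost", "ly", "qaly")
  stopifnot(all(need %in% names(surgery)), all(need %in% names(cmm)))
  d_cost <- surgery$cost - cmm$cost
  d_ly <- surgery$ly - cmm$ly
  d_qaly <- surgery$qaly - cmm$qaly
  icer <- NA_real_
  verdict <- if (d_qaly > 0) {
    if (d_cost <= 0) "dominant" else { icer <- d_cost / d_qaly; "icer" }
  } else if (d_qaly < 0) {
    if (d_cost >= 0) "dominated" else { icer <- d_cost / d_qaly; "icer" }
  } else {
    if (d_cost == 0) "equivalent" else "no_icer"
  }
  nmb <- wtp * d_qaly - d_cost
  structure(list(
    arms = data.frame(
      arm = c("surgery", "CMM"),
      cost = c(surgery$cost, cmm$cost),
      ly = c(surgery$ly, cmm$ly),
      qaly = c(surgery$qaly, cmm$qaly)
    ),
    d_cost = d_cost, d_ly = d_ly, d_qaly = d_qaly,
    icer = icer, verdict = verdict, wtp = wtp, nmb = nmb,
    cost_effective_at_wtp = nmb >= 0
  ), class = "baricea_cea")
}

#' @export
print.baricea_cea <- function(x, ...) {
  cat("Cost-effectiveness, surgery vs conventional medical management\n")
  a <- x$arms
  cat(sprintf("  %-8s cost %10.0f EUR   LY %6.2f   QALY %6.2f\n",
              a$arm, a$cost, a$ly, a$qaly))
  cat(sprintf("  increments: dC %.0f EUR, dLY %.2f, dQALY %.2f\n",
              x$d_cost, x$d_ly, x$d_qaly))
  if (x$verdict == "dominant") {
    cat("  verdict: surgery dominates (cheaper and more effective)\n")
  } else if (x$verdict == "dominated") {
    cat("  verdict: surgery dominated\n")
  } else if (x$verdict == "icer") {
    cat(sprintf("  ICER: %.0f EUR/QALY\n", x$icer))
  } else {
    cat("  verdict:", x$verdict, "\n")
  }
  cat(sprintf("  %scost-effective at %.0f EUR/QALY (NMB %.0f EUR)\n",
              if (x$cost_effective_at_wtp) "" else "not ", x$wtp, x$nmb))
  invisible(x)
}

#' Export a cost-effectiveness result as a delimited table
#'
#' @param cea a `baricea_cea`.
#' @param path optional TSV path.
#' @return data frame mirroring the standard reporting columns (per-arm
#'   cost, increments, LY, QALY, ICER/verdict).
#' @export
export_cea <- function(cea, path = NULL) {
  df <- data.frame(
    arm = cea$arms$arm, cost = cea$arms$cost,
    d_cost = c(cea$d_cost, NA), ly = cea$arms$ly, d_ly = c(cea$d_ly, NA),
    qaly = cea$arms$qaly, d_qaly = c(cea$d_qaly, NA),
    icer = c(if (cea$verdict == "icer") cea$icer else NA, NA),
    verdict = c(cea$verdict, NA)
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Extrapolate per-patient increments to a treated population
#'
#' @param increments a `baricea_cea` (or list with `d_cost`, `d_ly`,
#'   `d_qaly`).
#' @param n_patients number of treated patients (`>= 0`).
#' @return list with `total_savings` (euros; positive = money saved),
#'   `person_years` and `qalys` gained.
#' @export
population_extrapolation <- function(increments, n_patients) {
  stopifnot(n_patients >= 0)
  list(total_savings = -increments$d_cost * n_patients,
       person_years = increments$d_ly * n_patients,
       qalys = increments$d_qaly * n_patients)
}
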