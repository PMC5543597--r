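# Scenario orchestration: base case, delayed surgery, subgroup batches,
# run manifests.

#' Run both arms and compute the incremental results
#'
#' Convenience wrapper: builds the two [model_context()]s (sharing the
#' risk coefficients and life table derived from `params`), simulates both
#' arms, and returns the incremental cost-effectiveness at the requested
#' horizon.
#'
#' @inheritParams evaluate_model
#' @param delay_years years the cohort spends under conventional
#'   management before moving to the surgical arm (0 = immediate surgery).
#' @return list with `cea` (a `baricea_cea`), `surgery_run`, `cmm_run`,
#'   and the per-arm summaries.
#' @export
run_comparison <- function(params, profile = NULL,
                           horizon_months = "lifetime", procedure = "mix",
                           delay_years = 0, wtp = NULL) {
  evaluate_model(params, profile = profile,
                 horizon_months = horizon_months, procedure = procedure,
                 delay_years = delay_years, wtp = wtp)
}

#' Absolute and relative event risks per arm
#'
#' Cumulative incidence (fraction of the initial cohort experiencing a
#' first event) per event type and arm over the given horizon, and the
#' surgery/comparator relative risk. Non-fatal and fatal myocardial
#' infarctions and strokes are reported separately; diabetes counts new
#' onsets (not baseline prevalence or post-remission relapses).
#'
#' @param surgery_run,cmm_run [simulate_arm()] results for the two arms.
#' @param horizon_months optional truncation in cycles.
#' @return data frame with columns `event`, `risk_surgery`, `risk_cmm`,
#'   `relative_risk`.
#' @export
event_risk_table <- function(surgery_run, cmm_run, horizon_months = NULL) {
  cum_risks <- function(run) {
    H <- run$ctx$horizon
    keep <- seq_len(if (is.null(horizon_months)) H
                    else min(H, as.integer(horizon_months)))
    f <- run$flows
    nf <- colSums(f$ev_nf[keep, , drop = FALSE])
    ft <- colSums(f$ev_f[keep, , drop = FALSE])
    c(angina = nf[["angina"]],
      mi_nonfatal = nf[["mi"]], mi_fatal = ft[["mi"]],
      stroke_nonfatal = nf[["stroke"]], stroke_fatal = ft[["stroke"]],
      tia = sum(f$tia[keep]), hf = nf[["hf"]], pad = nf[["pad"]],
      t2d = sum(f$dm_inc[keep]))
  }
  rs <- cum_risks(surgery_run)
  rc <- cum_risks(cmm_run)
  data.frame(event = names(rs), risk_surgery = unname(rs),
             risk_cmm = unname(rc),
             relative_risk = unname(ifelse(rc > 0, rs / rc, NA_real_)),
             stringsAsFactors = FALSE)
}

#' Base-case analysis
#'
#' Runs the surgery (procedure mix) and conventional-management arms for
#' the given cohort and reports discounted cost, life years and QALYs per
#' arm with increments and the ICER/dominance verdict at the 10-year and
#' lifetime horizons, plus the absolute/relative event-risk table at both
#' horizons.
#'
#' @param params a `baricea_parameter_set`.
#' @param profile a [cohort_profile()] (default: reference cohort).
#' @param horizon `"lifetime"` (default; the 10-year view is extracted
#'   from the same run) or `"10y"` (runs exactly 120 cycles).
#' @param procedure surgical procedure or `"mix"`.
#' @param outdir optional directory; when given, result tables and a run
#'   manifest are written there.
#' @param seed recorded in the manifest (the base case itself is
#'   deterministic).
#' @return object of class `baricea_basecase`: list with `cea_10y`,
#'   `cea_lifetime` (NULL for `horizon = "10y"`), `risks_10y`,
#'   `risks_lifetime`, `surgery_run`, `cmm_run`.
#' @export
run_base_case <- function(params, profile = NULL, horizon = "lifetime",
                          procedure = "mix", outdir = NULL, seed = 0L) {
  horizon <- match.arg(horizon, c("lifetime", "10y"))
  profile <- profile %||% reference_profile(params)
  H <- if (horizon == "10y") 120L else "lifetime"
  res <- evaluate_model(params, profile = profile, horizon_months = H,
                        procedure = procedure)
  disc <- discount_spec(param_value(params, "discount_rate"))
  wtp <- param_value(params, "wtp_threshold")
  cea_10 <- compute_cea(arm_summary(res$surgery_run, disc, horizon = 120L),
                        arm_summary(res$cmm_run, disc, horizon = 120L),
                        wtp = wtp)
  cea_lt <- if (horizon == "lifetime") res$cea else NULL
  out <- structure(list(
    cea_10y = cea_10, cea_lifetime = cea_lt,
    risks_10y = event_risk_table(res$surgery_run, res$cmm_run, 120L),
    risks_lifetime = if (horizon == "lifetime") {
      event_risk_table(res$surgery_run, res$cmm_run)
    } else NULL,
    surgery_run = res$surgery_run, cmm_run = res$cmm_run,
    profile = profile
  ), class = "baricea_basecase")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    export_cea(cea_10, file.path(outdir, "cea_10y.tsv"))
    if (!is.null(cea_lt)) export_cea(cea_lt, file.path(outdir, "cea_lifetime.tsv"))
    utils::write.table(out$risks_10y, file.path(outdir, "risks_10y.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out$risks_lifetime)) {
      utils::write.table(out$risks_lifetime,
                         file.path(outdir, "risks_lifetime.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_run_manifest(outdir, seed, params,
                       extra = list(analysis = "basecase",
                                    horizon = horizon))
  }
  out
}

#' @export
print.baricea_basecase <- function(x, ...) {
  cat("=== 10-year horizon ===\n"); print(x$cea_10y)
  if (!is.null(x$cea_lifetime)) {
    cat("=== lifetime horizon ===\n"); print(x$cea_lifetime)
  }
  invisible(x)
}

#' Delayed-surgery scenarios
#'
#' The cohort starts under conventional management and moves to the
#' surgical arm after `delay_years` years; during the delay it accrues
#' comparator costs, events and mortality, and the survivors carry their
#' evolved risk-factor levels and condition mix into surgery (the
#' procedure tariff is charged, and discounted, at the delay boundary).
#' Each delay is compared against the same conventional-management arm
#' over a lifetime horizon.
#'
#' @param params a `baricea_parameter_set`.
#' @param delays vector of whole-year delays (default `0:3`).
#' @param profile cohort (default: the non-diabetic reference cohort, the
#'   standard waiting-list population).
#' @param procedure surgical procedure or `"mix"`.
#' @return object of class `baricea_delay`: data frame with one row per
#'   delay (`delay_years`, surgery-arm `cost`, `ly`, `qaly`, increments
#'   vs. the comparator, and losses vs. immediate surgery), with the runs
#'   in attributes.
#' @export
run_delay_scenario <- function(params, delays = 0:3, profile = NULL,
                               procedure = "mix") {
  stopifnot(all(delays >= 0), all(delays == floor(delays)))
  if (is.null(profile)) {
    ref <- reference_profile(params)
    profile <- cohort_profile(ref$age, ref$male, ref$bmi, ref$sbp,
                              diabetic = 0, smoker = ref$smoker)
  }
  coeffs <- default_risk_coefficients(params)
  lt <- life_table_from_params(params)
  space <- build_state_space()
  disc <- discount_spec(param_value(params, "discount_rate"))
  wtp <- param_value(params, "wtp_threshold")

  ctx_c <- model_context(params, profile, arm = "CMM",
                         procedure = procedure, coeffs = coeffs,
                         life_table = lt, space = space)
  cmm_sum <- arm_summary(simulate_arm(ctx_c), disc)

  runs <- list()
  rows <- lapply(delays, function(d) {
    ctx_s <- model_context(params, profile, arm = "surgery",
                           procedure = procedure,
                           surgery_month = 12L * d + 1L, coeffs = coeffs,
                           life_table = lt, space = space)
    run <- simulate_arm(ctx_s)
    runs[[as.character(d)]] <<- run
    s <- arm_summary(run, disc)
    cea <- compute_cea(s, cmm_sum, wtp = wtp)
    data.frame(delay_years = d, cost = s$cost, ly = s$ly, qaly = s$qaly,
               d_cost = cea$d_cost, d_ly = cea$d_ly, d_qaly = cea$d_qaly,
               verdict = cea$verdict)
  })
  df <- do.call(rbind, rows)
  df$ly_lost_vs_immediate <- df$ly[df$delay_years == min(delays)] - df$ly
  df$qaly_lost_vs_immediate <- df$qaly[df$delay_years == min(delays)] - df$qaly
  rownames(df) <- NULL
  attr(df, "cmm") <- cmm_sum
  attr(df, "runs") <- runs
  class(df) <- c("baricea_delay", "data.frame")
  df
}

#' Subgroup batch: 16 cohorts
#'
#' The standard subgroup grid: 41-year-old non-smoking males and females
#' with baseline BMI 33 (severe), 37 (moderate), 42 (morbid) and 52
#' (super obesity) kg/m^2, with and without established type 2 diabetes
#' (2 x 4 x 2 = 16 cohorts). Each cohort is run over a lifetime and the
#' verdict is reported at the 10-year and lifetime horizons.
#'
#' @param params a `baricea_parameter_set`.
#' @param bmi_levels baseline BMI levels of the grid.
#' @param age,smoker,sbp fixed cohort characteristics of the grid.
#' @param procedure surgical procedure or `"mix"`.
#' @return data frame with one row per cohort: `sex`, `bmi`, `diabetic`,
#'   and per horizon the increments and ICER/verdict.
#' @export
run_subgroup_batch <- function(params, bmi_levels = c(33, 37, 42, 52),
                               age = 41, smoker = 0, sbp = NULL,
                               procedure = "mix") {
  sbp <- sbp %||% param_value(params, "sbp_baseline")
  coeffs <- default_risk_coefficients(params)
  lt <- life_table_from_params(params)
  space <- build_state_space()
  disc <- discount_spec(param_value(params, "discount_rate"))
  wtp <- param_value(params, "wtp_threshold")

  grid <- expand.grid(male = c(1, 0), bmi = bmi_levels, diabetic = c(0, 1))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    profile <- cohort_profile(age, g$male, g$bmi, sbp, g$diabetic, smoker)
    ctx_s <- model_context(params, profile, arm = "surgery",
                           procedure = procedure, coeffs = coeffs,
                           life_table = lt, space = space)
    ctx_c <- model_context(params, profile, arm = "CMM",
                           procedure = procedure, coeffs = coeffs,
                           life_table = lt, space = space)
    run_s <- simulate_arm(ctx_s); run_c <- simulate_arm(ctx_c)
    lt_cea <- compute_cea(arm_summary(run_s, disc), arm_summary(run_c, disc),
                          wtp = wtp)
    y10_cea <- compute_cea(arm_summary(run_s, disc, horizon = 120L),
                           arm_summary(run_c, disc, horizon = 120L),
                           wtp = wtp)
    fmt <- function(cea) data.frame(
      d_cost = cea$d_cost, d_qaly = cea$d_qaly,
      icer = if (cea$verdict == "icer") cea$icer else NA_real_,
      verdict = cea$verdict)
    y10 <- fmt(y10_cea); names(y10) <- paste0(names(y10), "_10y")
    lft <- fmt(lt_cea); names(lft) <- paste0(names(lft), "_lifetime")
    cbind(data.frame(sex = if (g$male == 1) "male" else "female",
                     bmi = g$bmi, diabetic = g$diabetic), y10, lft)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: seed, an MD5 hash of the
#' canonical serialised configuration, and the package version. Identical
#' manifests imply identical outputs.
#'
#' @param outdir output directory (created if needed).
#' @param seed the seed used for the run.
#' @param params the `baricea_parameter_set` used.
#' @param extra named list of additional fields (analysis name, horizon,
#'   iteration counts, ...).
#' @return the manifest list, invisibly; written to
#'   `<outdir>/manifest.json`.
#' @export
write_run_manifest <- function(outdir, seed, params, extra = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_parameter_set(params, tmp)
  manifest <- c(list(
    package = "baricea",
    version = as.character(utils::packageVersion("baricea")),
    seed = as.integer(seed),
    config_md5 = unname(tools::md5sum(tmp))
  ), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Calibration harness for the placeholder risk equations
#'
#' Runs the comparator arm for the reference cohort over 10 years and
#' reports, for each event, the ratio of the model's cumulative risk to
#' the literature reference value the placeholder coefficients were
#' calibrated against. Ratios are reported, not asserted: the packaged
#' coefficients claim order-of-magnitude calibration only (the true
#' risk-equation coefficients are not published).
#'
#' @param params a `baricea_parameter_set`.
#' @param reference_risks named vector of 10-year comparator-arm
#'   cumulative risks used as calibration reference.
#' @param profile cohort (default: reference profile).
#' @return data frame with columns `event`, `model_risk`,
#'   `reference_risk`, `ratio`.
#' @export
calibration_report <- function(params,
                               reference_risks = c(
                                 angina = 0.03, mi_nonfatal = 0.06,
                                 mi_fatal = 0.001, stroke_nonfatal = 0.03,
                                 stroke_fatal = 0.0056, tia = 0.005,
                                 hf = 0.03, pad = 0.03, t2d = 0.23),
                               profile = NULL) {
  res <- evaluate_model(params, profile = profile, horizon_months = 120L)
  risks <- event_risk_table(res$surgery_run, res$cmm_run, 120L)
  m <- risks$risk_cmm[match(names(reference_risks), risks$event)]
  data.frame(event = names(reference_risks), model_risk = m,
             reference_risk = unname(reference_risks),
             ratio = m / unname(reference_risks),
             stringsAsFactors = FALSE)
}
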