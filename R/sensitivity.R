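# Deterministic and probabilistic sensitivity analysis.

# internal: evaluate one full surgery-vs-comparator comparison for a
# parameter set (used by DSA and PSA); profile defaults to the cohort
# implied by the baseline-characteristic parameters
evaluate_model <- function(params, profile = NULL,
                           horizon_months = "lifetime", procedure = "mix",
                           delay_years = 0, space = NULL, wtp = NULL) {
  profile <- profile %||% reference_profile(params)
  wtp <- wtp %||% param_value(params, "wtp_threshold")
  coeffs <- default_risk_coefficients(params)
  lt <- life_table_from_params(params)
  space <- space %||% build_state_space()
  s0 <- 12L * as.integer(delay_years) + 1L
  ctx_s <- model_context(params, profile, arm = "surgery",
                         procedure = procedure,
                         horizon_months = horizon_months,
                         surgery_month = s0, coeffs = coeffs,
                         life_table = lt, space = space)
  ctx_c <- model_context(params, profile, arm = "CMM",
                         procedure = procedure,
                         horizon_months = horizon_months,
                         coeffs = coeffs, life_table = lt, space = space)
  run_s <- simulate_arm(ctx_s)
  run_c <- simulate_arm(ctx_c)
  disc <- discount_spec(param_value(params, "discount_rate"))
  list(surgery_run = run_s, cmm_run = run_c,
       surgery = arm_summary(run_s, disc), cmm = arm_summary(run_c, disc),
       cea = compute_cea(arm_summary(run_s, disc), arm_summary(run_c, disc),
                         wtp = wtp),
       wtp = wtp)
}

# internal: DSA/tornado outcome of a comparison: the ICER where defined,
# the incremental net monetary benefit otherwise
dsa_outcome <- function(cea) {
  if (cea$verdict == "icer") c(icer = cea$icer, nmb = cea$nmb)
  else c(icer = NA_real_, nmb = cea$nmb)
}

#' One-way deterministic sensitivity analysis
#'
#' Varies each parameter that carries a deterministic range one at a time
#' to its low and high bound (binary cohort flags use 0/1 as their
#' bounds), re-running the full comparison while all other parameters stay
#' at their point estimates, and restoring the base value afterwards. The
#' reported outcome is the ICER where defined at the base and both bounds,
#' and the incremental net monetary benefit (NMB) at the willingness-to-pay
#' threshold otherwise (a dominant result has no ICER). Entries whose
#' swing exceeds `swing_threshold` euros are flagged for the headline
#' tornado figure; the full list is always returned.
#'
#' @param params a `baricea_parameter_set`.
#' @param parameters names to vary (default: all parameters with a range).
#' @param horizon_months `"lifetime"` or a cycle count.
#' @param dsa_cohort use the standard one-way-analysis cohort (male,
#'   non-smoking, diabetes-free at the reference age/BMI/SBP) by setting
#'   the corresponding binary parameters before the analysis.
#' @param swing_threshold euros; inclusion threshold for the headline
#'   figure.
#' @param procedure surgical procedure or `"mix"`.
#' @return object of class `baricea_dsa`: data frame with one row per
#'   varied parameter (`parameter`, `low`, `high`, `outcome_low`,
#'   `outcome_high`, `nmb_low`, `nmb_high`, `metric`, `swing`,
#'   `included`), with the base-case outcome in attributes.
#' @export
one_way_dsa <- function(params, parameters = NULL,
                        horizon_months = "lifetime", dsa_cohort = TRUE,
                        swing_threshold = 100, procedure = "mix") {
  if (dsa_cohort) {
    params <- set_param_value(params, "male_fraction", 1)
    params <- set_param_value(params, "smoking_prevalence", 0)
    params <- set_param_value(params, "diabetes_prevalence", 0)
  }
  parameters <- parameters %||% dsa_parameter_names(params)
  missing_range <- parameters[!parameters %in% dsa_parameter_names(params)]
  if (length(missing_range)) {
    warning("skipping parameter(s) without a DSA range: ",
            paste(missing_range, collapse = ", "))
    parameters <- setdiff(parameters, missing_range)
  }
  space <- build_state_space()
  base <- evaluate_model(params, horizon_months = horizon_months,
                         procedure = procedure, space = space)
  base_out <- dsa_outcome(base$cea)

  rows <- lapply(parameters, function(nm) {
    p <- params$parameters[[nm]]
    out <- lapply(c(low = p$low, high = p$high), function(v) {
      dsa_outcome(evaluate_model(set_param_value(params, nm, v),
                                 horizon_months = horizon_months,
                                 procedure = procedure,
                                 space = space)$cea)
    })
    use_icer <- !is.na(base_out[["icer"]]) &&
      !is.na(out$low[["icer"]]) && !is.na(out$high[["icer"]])
    metric <- if (use_icer) "icer" else "nmb"
    ol <- out$low[[metric]]; oh <- out$high[[metric]]
    data.frame(parameter = nm, low = p$low, high = p$high,
               outcome_low = ol, outcome_high = oh,
               icer_low = out$low[["icer"]], icer_high = out$high[["icer"]],
               nmb_low = out$low[["nmb"]], nmb_high = out$high[["nmb"]],
               metric = metric, swing = abs(oh - ol),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$included <- df$swing > swing_threshold
  df <- df[order(-df$swing), ]
  rownames(df) <- NULL
  attr(df, "base_icer") <- base_out[["icer"]]
  attr(df, "base_nmb") <- base_out[["nmb"]]
  attr(df, "base_verdict") <- base$cea$verdict
  attr(df, "wtp") <- base$wtp
  class(df) <- c("baricea_dsa", "data.frame")
  df
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param dsa a [one_way_dsa()] result.
#' @param top number of (included) parameters shown.
#' @return a ggplot object.
#' @export
plot_tornado <- function(dsa, top = 15) {
  df <- dsa[dsa$included, , drop = FALSE]
  df <- utils::head(df, top)
  if (!nrow(df)) stop("no parameter exceeds the inclusion threshold")
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(dsa, "base_nmb")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = nmb_low, xend = nmb_high,
      y = parameter, yend = parameter), linewidth = 4,
      colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "incremental net monetary benefit (EUR)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

# internal: draw one value for a parameter, retrying until it respects
# its support (probabilities in [0, 1]; baseline characteristics within
# the cohort-profile bounds)
.psa_bounds <- list(
  age_baseline = c(18, 100), bmi_baseline = c(20, 80),
  sbp_baseline = c(90, 250)
)

draw_parameter <- function(p, max_retry = 100L) {
  kind <- .param_registry[[p$name]] %||% "other"
  lo <- -Inf; hi <- Inf
  if (kind == "probability") { lo <- 0; hi <- 1 }
  if (kind == "cost") lo <- 0
  if (kind == "positive") lo <- .Machine$double.eps
  if (!is.null(.psa_bounds[[p$name]])) {
    b <- .psa_bounds[[p$name]]; lo <- max(lo, b[1]); hi <- min(hi, b[2])
  }
  for (k in seq_len(max_retry)) {
    x <- sample_distribution(p$dist, 1L)
    if (x >= lo && x <= hi) return(x)
  }
  stop("could not draw a valid value for parameter '", p$name,
       "' after ", max_retry, " retries")
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte-Carlo sampling of every parameter that carries a PSA
#' distribution and is not flagged `psa_excluded` (reimbursement tariffs
#' are excluded); draws are independent across parameters. Each iteration
#' re-runs the full comparison and records the incremental cost and QALYs
#' and their classification: `cost_saving` (cheaper and more effective),
#' `cost_effective` (more effective with `0 <= ICER <= wtp`), or
#' `not_cost_effective`. One master seed generates a deterministic
#' per-iteration seed stream, so single iterations are replayable.
#'
#' @param params a `baricea_parameter_set`.
#' @param profile optional fixed [cohort_profile()]; when supplied the
#'   baseline-characteristic parameters are held at their point estimates
#'   (used e.g. for the diabetic / non-diabetic stratification), otherwise
#'   the cohort is re-drawn each iteration from the baseline
#'   distributions.
#' @param n_iter number of iterations (the reference analysis uses 5000).
#' @param seed master seed.
#' @param wtp willingness-to-pay threshold (default: the parameter set's).
#' @param horizon_months `"lifetime"` or a cycle count.
#' @param procedure surgical procedure or `"mix"`.
#' @return object of class `baricea_psa`: list with `samples` (data frame
#'   `iteration`, `d_cost`, `d_qaly`, `icer`, `class`), `draws` (matrix of
#'   drawn parameter values), and `summary` (the three fractions).
#' @export
run_psa <- function(params, profile = NULL, n_iter = 5000, seed = 1L,
                    wtp = NULL, horizon_months = "lifetime",
                    procedure = "mix") {
  stopifnot(n_iter >= 1)
  n_iter <- as.integer(n_iter)
  wtp <- wtp %||% param_value(params, "wtp_threshold")
  eligible <- sort(psa_parameter_names(params))
  if (!is.null(profile)) {
    eligible <- setdiff(eligible, c("age_baseline", "male_fraction",
                                    "sbp_baseline", "bmi_baseline",
                                    "diabetes_prevalence",
                                    "smoking_prevalence"))
  }
  if (!length(eligible)) stop("no PSA-eligible parameters in the set")
  space <- build_state_space()

  set.seed(as.integer(seed))
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)

  draws <- matrix(NA_real_, n_iter, length(eligible),
                  dimnames = list(NULL, eligible))
  d_cost <- d_qaly <- icer <- numeric(n_iter)
  klass <- character(n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(iter_seeds[i])
    pi <- params
    for (nm in eligible) {
      v <- draw_parameter(pi$parameters[[nm]])
      draws[i, nm] <- v
      pi <- set_param_value(pi, nm, v)
    }
    res <- evaluate_model(pi, profile = profile,
                          horizon_months = horizon_months,
                          procedure = procedure, space = space, wtp = wtp)
    d_cost[i] <- res$cea$d_cost
    d_qaly[i] <- res$cea$d_qaly
    icer[i] <- if (res$cea$verdict == "icer") res$cea$icer else NA_real_
    klass[i] <- if (d_qaly[i] > 0 && d_cost[i] < 0) "cost_saving"
      else if (d_qaly[i] > 0 && !is.na(icer[i]) && icer[i] <= wtp) "cost_effective"
      else "not_cost_effective"
  }
  samples <- data.frame(iteration = seq_len(n_iter), d_cost = d_cost,
                        d_qaly = d_qaly, icer = icer, class = klass,
                        stringsAsFactors = FALSE)
  structure(list(
    samples = samples, draws = draws, wtp = wtp, seed = seed,
    summary = c(cost_saving = mean(klass == "cost_saving"),
                cost_effective = mean(klass == "cost_effective"),
                not_cost_effective = mean(klass == "not_cost_effective"))
  ), class = "baricea_psa")
}

#' @export
print.baricea_psa <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<baricea PSA: %d iterations, WTP %.0f EUR/QALY>\n", n, x$wtp))
  cat(sprintf("  cost-saving:        %5.1f%%\n", 100 * x$summary[["cost_saving"]]))
  cat(sprintf("  cost-effective:     %5.1f%%\n", 100 * x$summary[["cost_effective"]]))
  cat(sprintf("  not cost-effective: %5.1f%%\n",
              100 * x$summary[["not_cost_effective"]]))
  invisible(x)
}

#' Export the cost-effectiveness plane
#'
#' @param psa a [run_psa()] result, or a data frame with `d_qaly`,
#'   `d_cost`.
#' @param path optional TSV path.
#' @param strata optional factor (same length as the samples) partitioning
#'   the points, e.g. by baseline diabetes status.
#' @return data frame of `(d_qaly, d_cost)` pairs (plus `stratum` when
#'   given), with quadrant counts (`NE`, `NW`, `SE`, `SW`; effect on the
#'   x-axis, cost on the y-axis) in the `"quadrants"` attribute.
#' @export
ce_plane_export <- function(psa, path = NULL, strata = NULL) {
  samples <- if (inherits(psa, "baricea_psa")) psa$samples else psa
  stopifnot(nrow(samples) >= 1)
  df <- data.frame(d_qaly = samples$d_qaly, d_cost = samples$d_cost)
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(df))
    df$stratum <- strata
  }
  quad <- c(
    NE = sum(df$d_qaly > 0 & df$d_cost > 0),
    NW = sum(df$d_qaly < 0 & df$d_cost > 0),
    SE = sum(df$d_qaly > 0 & df$d_cost < 0),
    SW = sum(df$d_qaly < 0 & df$d_cost < 0)
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  attr(df, "quadrants") <- quad
  df
}

#' Scatter plot of the cost-effectiveness plane
#'
#' @param psa a [run_psa()] result.
#' @param strata optional factor colouring the points.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(psa, strata = NULL) {
  df <- ce_plane_export(psa, strata = strata)
  p <- if (is.null(strata)) {
    ggplot2::ggplot(df, ggplot2::aes(d_qaly, d_cost))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(d_qaly, d_cost, colour = stratum))
  }
  p + ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "incremental QALYs", y = "incremental cost (EUR)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA iterations with non-negative incremental net monetary
#' benefit `wtp * dQALY - dCost` at each willingness-to-pay value.
#'
#' @param psa a [run_psa()] result.
#' @param wtp_grid willingness-to-pay values (euros/QALY).
#' @return data frame with columns `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 5000)) {
  s <- psa$samples
  prob <- vapply(wtp_grid, function(w)
    mean(w * s$d_qaly - s$d_cost >= 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}
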