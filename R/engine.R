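# Markov engine.
#
# The transition structure (which state can flow to which) is fixed by the
# state space; only the per-cycle probabilities vary with time as the
# cohort ages and its BMI/SBP trajectories evolve. The engine therefore
# precomputes an edge list once per state space (cached), precomputes the
# per-cycle inputs (baseline event probabilities per trajectory group and
# diabetes status, background mortality, diabetes incidence and remission
# schedules) once per run, and fills the edge probabilities each cycle by
# vectorised indexing, propagating the occupancy by flow accumulation
# (base::rowsum). Building the explicit dense transition matrix
# (build_transition_matrix) uses the same edge probabilities, and
# agreement of the two paths is part of the test suite.

# edge type codes
.EV_NF <- 1L; .EV_F <- 2L; .DM_INC <- 3L; .DM_REM <- 4L; .DM_REINC <- 5L
.CONV <- 6L; .DIE_BG <- 7L; .DIE_X <- 8L; .STAY <- 9L

.engine_cache <- new.env(parent = emptyenv())

space_signature <- function(space) {
  cfg <- space$config
  paste(paste(cfg$conditions, collapse = ","), cfg$diabetes, cfg$conversion,
        cfg$cvd_cap, cfg$stroke_tunnel_years, sep = "|")
}

# internal: build (and cache) the edge list and the parameter-independent
# per-state attributes of a state space
engine_edges <- function(space) {
  sig <- space_signature(space)
  if (!is.null(.engine_cache[[sig]])) return(.engine_cache[[sig]])

  st <- space$states
  living <- which(st$alive)
  nL <- length(living)
  i_dead_cvd <- if (any(st$dead_type == "cvd")) which(st$dead_type == "cvd") else NA_integer_
  i_dead_other <- which(st$dead_type == "other")
  chronic <- space$chronic_phase
  cap <- space$config$cvd_cap
  conds_enabled <- space$config$conditions
  has_dm <- space$config$diabetes
  has_conv <- space$config$conversion

  from <- integer(0); to <- integer(0); type <- integer(0); event <- integer(0)
  add <- function(f, t, ty, ev = 0L) {
    from <<- c(from, f); to <<- c(to, t); type <<- c(type, ty)
    event <<- c(event, ev)
  }
  adv <- function(ph) if (ph == 0L) 0L else min(ph + 1L, chronic)

  for (i in living) {
    track <- st$track[i]; dm <- st$dm[i]
    S <- split_conds(st$conds[i]); ph <- st$st_phase[i]
    ph2 <- adv(ph)
    key2 <- function(s) paste(sort(s), collapse = "+")

    if (length(S) < cap) {
      for (e in setdiff(conds_enabled, S)) {
        nph <- if (e == "stroke") 1L else ph2
        dest <- state_id(space, track, dm, key2(c(S, e)), nph)
        ei <- match(e, .cvd_events)
        add(i, dest, .EV_NF, ei)
        if (e %in% c("mi", "stroke") && !is.na(i_dead_cvd)) {
          add(i, i_dead_cvd, .EV_F, ei)
        }
      }
    }
    if (has_dm) {
      if (dm == "ND") {
        add(i, state_id(space, track, "T2D", key2(S), ph2), .DM_INC)
      } else if (dm == "T2D" && track != "CMM") {
        add(i, state_id(space, track, "REM", key2(S), ph2), .DM_REM)
      } else if (dm == "REM") {
        add(i, state_id(space, track, "T2D", key2(S), ph2), .DM_REINC)
      }
    }
    if (has_conv && track %in% c("SURG", "COMP")) {
      add(i, state_id(space, "CONV", dm, key2(S), ph2), .CONV)
    }
    add(i, i_dead_other, .DIE_BG)
    if (!is.na(i_dead_cvd) && (length(S) > 0 || dm == "T2D")) {
      add(i, i_dead_cvd, .DIE_X)
    }
    add(i, state_id(space, track, dm, key2(S), ph2), .STAY)
  }

  gfrom <- match(from, living)
  tou <- sort(unique(to))
  edges <- list(
    from = from, to = to, type = type, event = event,
    gfrom = gfrom, gto = match(to, tou), tou = tou,
    living = living, i_dead_cvd = i_dead_cvd, i_dead_other = i_dead_other,
    i_dead = which(!st$alive),
    idx = lapply(stats::setNames(1:9, c("ev_nf", "ev_f", "dm_inc", "dm_rem",
                                        "dm_reinc", "conv", "die_bg", "die_x",
                                        "stay")),
                 function(ty) which(type == ty)),
    nonstay = which(type != .STAY)
  )
  # per-event edge indices for probability filling and flow accounting
  edges$ev_nf_by_event <- lapply(seq_along(.cvd_events), function(ei)
    edges$idx$ev_nf[event[edges$idx$ev_nf] == ei])
  edges$ev_f_by_event <- lapply(seq_along(.cvd_events), function(ei)
    edges$idx$ev_f[event[edges$idx$ev_f] == ei])
  # stay edge of each living state, in living order
  stay_idx <- edges$idx$stay
  edges$stay_by_living <- stay_idx[match(seq_len(nL), gfrom[stay_idx])]

  # parameter-independent per-state attributes
  track_l <- st$track[living]
  edges$grp <- ifelse(track_l == "CMM", 1L, ifelse(track_l == "CONV", 3L, 2L))
  edges$dm_l <- st$dm[living]
  edges$dm01 <- as.integer(edges$dm_l == "T2D")
  cond_mat <- vapply(.cvd_conditions, function(cn)
    vapply(st$conds[living], function(k) cn %in% split_conds(k), logical(1)),
    logical(nL))
  dimnames(cond_mat) <- list(NULL, .cvd_conditions)
  edges$cond_mat <- cond_mat
  edges$track_l <- track_l

  # surgery-cycle routing maps (comparator-track living states)
  cmm_living <- living[track_l == "CMM"]
  edges$cmm_living <- cmm_living
  edges$map_surg <- vapply(cmm_living, function(i)
    state_id(space, "SURG", st$dm[i], st$conds[i], st$st_phase[i]), integer(1))
  edges$map_comp <- vapply(cmm_living, function(i)
    state_id(space, "COMP", st$dm[i], st$conds[i], st$st_phase[i]), integer(1))

  .engine_cache[[sig]] <- edges
  edges
}

#' Lifetime simulation horizon for a cohort
#'
#' Months until the cohort reaches the life-table closure age of 110.
#'
#' @param profile a [cohort_profile()].
#' @return number of monthly cycles.
#' @export
lifetime_horizon <- function(profile) as.integer(floor((110 - profile$age) * 12))

#' Assemble a model context for one arm
#'
#' Precomputes everything a cohort run needs: the state space and its edge
#' list, risk-factor trajectories per trajectory group (comparator,
#' post-surgery, post-conversion), per-state comorbidity and mortality
#' multipliers, the per-cycle baseline event probabilities and
#' cause-deleted background mortality, surgical outcome probabilities and
#' the initial occupancy.
#'
#' @param params a `baricea_parameter_set`.
#' @param profile a [cohort_profile()] (default: the reference profile of
#'   `params`).
#' @param arm `"surgery"` or `"CMM"`.
#' @param procedure `"GBP"`, `"SG"`, `"AGB"` or `"mix"`.
#' @param horizon_months number of cycles, `"10y"` (120 cycles), or
#'   `"lifetime"` (to age 110).
#' @param surgery_month cycle of surgery (delayed-surgery scenarios use
#'   `12 * delay_years + 1`).
#' @param coeffs risk coefficients (default [default_risk_coefficients()]
#'   built from `params`).
#' @param life_table background life table (default: generated from the
#'   life-table parameters of `params`).
#' @param space a [build_state_space()] result (default configuration when
#'   omitted).
#' @return an object of class `baricea_context`.
#' @export
model_context <- function(params, profile = NULL,
                          arm = c("surgery", "CMM"), procedure = "mix",
                          horizon_months = "lifetime", surgery_month = 1L,
                          coeffs = NULL, life_table = NULL, space = NULL) {
  arm <- match.arg(arm)
  procedure <- match.arg(procedure, .procedures)
  profile <- profile %||% reference_profile(params)
  coeffs <- coeffs %||% default_risk_coefficients(params)
  life_table <- life_table %||% life_table_from_params(params)
  space <- space %||% build_state_space()
  H <- if (identical(horizon_months, "lifetime")) lifetime_horizon(profile)
       else if (identical(horizon_months, "10y")) 120L
       else as.integer(horizon_months)
  stopifnot(H >= 1)
  s0 <- if (arm == "CMM") Inf else as.integer(surgery_month)

  edges <- engine_edges(space)
  nL <- length(edges$living)

  # comorbidity relative-risk multiplier per living state x event
  cond_mat <- edges$cond_mat
  ncond <- rowSums(cond_mat)
  g <- coeffs$comorbidity_rr$generic
  rrmult <- matrix(g^ncond, nL, length(.cvd_events),
                   dimnames = list(NULL, .cvd_events))
  hf <- cond_mat[, "hf"]
  rrmult[hf, "stroke"] <- rrmult[hf, "stroke"] / g *
    coeffs$comorbidity_rr$hf_stroke
  # few distinct multiplier values per event: index into level tables so
  # the annual-to-monthly conversion runs on small matrices each cycle
  rr_levels <- lapply(seq_along(.cvd_events), function(e) {
    u <- sort(unique(rrmult[, e]))
    list(values = u, idx = match(rrmult[, e], u))
  })

  # chronic mortality multiplier per living state
  mrr <- coeffs$mortality_rr
  logm <- as.vector(cond_mat %*% log(mrr[.cvd_conditions]))
  mort_mult <- exp(logm) * ifelse(edges$dm01 == 1, mrr[["t2d"]], 1)

  # trajectories per group (1 = comparator, 2 = post-surgery,
  # 3 = post-conversion on the bypass curve)
  cmm_bmi <- bmi_trajectory(profile, "CMM", procedure, H, params)$values
  if (arm == "surgery") {
    surg_bmi <- bmi_trajectory(profile, "surgery", procedure, H, params,
                               surgery_month = s0)$values
    conv_bmi <- bmi_trajectory(profile, "surgery", "GBP", H, params,
                               surgery_month = s0)$values
  } else {
    surg_bmi <- conv_bmi <- cmm_bmi
  }
  bmi <- rbind(cmm = cmm_bmi, surg = surg_bmi, conv = conv_bmi)
  sbp <- array(dim = c(3, 2, H + 1))
  for (d in 0:1) {
    cmm_sbp <- sbp_trajectory(profile, "CMM", d == 1, H, params)$values
    if (arm == "surgery") {
      s_sbp <- sbp_trajectory(profile, "surgery", d == 1, H, params,
                              surgery_month = s0)$values
    } else s_sbp <- cmm_sbp
    sbp[1, d + 1, ] <- cmm_sbp
    sbp[2, d + 1, ] <- s_sbp
    sbp[3, d + 1, ] <- s_sbp
  }

  # cause-deleted background mortality by integer age (vectorised)
  lt <- life_table
  ord_m <- lt$sex == "male"
  qdel_m <- (lt$q_all_cause * (1 - lt$ihd_fraction))[ord_m][order(lt$age[ord_m])]
  ord_f <- lt$sex == "female"
  qdel_f <- (lt$q_all_cause * (1 - lt$ihd_fraction))[ord_f][order(lt$age[ord_f])]

  # per-cycle inputs
  t <- seq_len(H)
  age_t <- profile$age + (t - 1) / 12
  ai <- pmin(110L, pmax(0L, as.integer(floor(age_t))))
  q_ann <- profile$male * qdel_m[ai + 1L] + (1 - profile$male) * qdel_f[ai + 1L]
  qm <- 1 - (1 - q_ann)^(1 / 12)

  # baseline annual event probabilities: events x (group, diabetes) x cycle
  base_ann <- array(0, dim = c(length(.cvd_events), 6L, H))
  for (gi in 1:3) for (d in 0:1) {
    X <- rbind(age_t - 40, profile$male, sbp[gi, d + 1L, t + 1L] - 120,
               bmi_score(bmi[gi, t + 1L], coeffs$bmi_entry), d,
               profile$smoker)
    base_ann[, (gi - 1L) * 2L + d + 1L, ] <-
      stats::plogis(coeffs$intercepts + coeffs$coefficients %*% X)
  }
  inc_m <- 1 - (1 - rbind(
    t2d_incidence_annual(bmi[1, t + 1L], coeffs),
    t2d_incidence_annual(bmi[2, t + 1L], coeffs),
    t2d_incidence_annual(bmi[3, t + 1L], coeffs)))^(1 / 12)
  rem_m <- if (is.finite(s0)) {
    t2d_remission_probability(pmax(t - s0, 0), params, arm = "surgery")
  } else numeric(H)

  outc <- surgical_cycle_outcomes(procedure, params)

  # initial occupancy: comparator track, no CVD, diabetes split
  v0 <- numeric(space$n)
  d0 <- if (space$config$diabetes) profile$diabetic else 0
  v0[state_id(space, "CMM", "ND", "", 0L)] <- 1 - d0
  if (space$config$diabetes) {
    v0[state_id(space, "CMM", "T2D", "", 0L)] <- d0
  }

  e <- edges
  combo <- (e$grp - 1L) * 2L + e$dm01 + 1L
  ctx <- structure(list(
    params = params, profile = profile, arm = arm, procedure = procedure,
    horizon = H, s0 = s0, coeffs = coeffs, life_table = life_table,
    space = space, edges = edges, nL = nL, grp = e$grp, dm01 = e$dm01,
    combo = combo, cond_mat = cond_mat, rrmult = rrmult,
    rr_levels = rr_levels, mort_mult = mort_mult,
    bmi = bmi, sbp = sbp, qdel_m = qdel_m, qdel_f = qdel_f, qm = qm,
    base_ann = base_ann, inc_m = inc_m, rem_m = rem_m,
    outcomes = outc,
    conv_m = annual_to_cycle_probability(outc$annual_conversion, 12L),
    v0 = v0, cmm_living = e$cmm_living,
    map_surg = e$map_surg, map_comp = e$map_comp,
    age0 = profile$age,
    # per-edge precomputed lookups
    pre = list(
      ev_nf_combo = lapply(e$ev_nf_by_event, function(i) combo[e$gfrom[i]]),
      ev_nf_lvl = lapply(seq_along(.cvd_events), function(k)
        rr_levels[[k]]$idx[e$gfrom[e$ev_nf_by_event[[k]]]]),
      ev_f_combo = lapply(e$ev_f_by_event, function(i) combo[e$gfrom[i]]),
      ev_f_lvl = lapply(seq_along(.cvd_events), function(k)
        rr_levels[[k]]$idx[e$gfrom[e$ev_f_by_event[[k]]]]),
      dm_inc_grp = e$grp[e$gfrom[e$idx$dm_inc]],
      dm_reinc_grp = e$grp[e$gfrom[e$idx$dm_reinc]],
      die_x_mm1 = mort_mult[e$gfrom[e$idx$die_x]] - 1,
      tia_combo = combo,
      tia_lvl = rr_levels[[match("tia", .cvd_events)]]$idx
    )
  ), class = "baricea_context")
  ctx
}

# internal: per-cycle edge probabilities (excluding the surgery-cycle
# routing, which is handled separately), plus the transient-TIA
# probability per living state
cycle_probs <- function(ctx, t) {
  e <- ctx$edges
  cf <- ctx$coeffs$case_fatality[.cvd_events]
  qm <- ctx$qm[t]
  nEv <- length(.cvd_events)

  pe <- numeric(length(e$from))
  # events: convert annual -> monthly on the small (combo x rr-level) grid
  pm_small <- vector("list", nEv)
  for (k in seq_len(nEv)) {
    lv <- ctx$rr_levels[[k]]$values
    ann <- pmin(outer(ctx$base_ann[k, , t], lv), 1)
    pm_small[[k]] <- 1 - (1 - ann)^(1 / 12)
    i <- e$ev_nf_by_event[[k]]
    if (length(i)) {
      pe[i] <- pm_small[[k]][cbind(ctx$pre$ev_nf_combo[[k]],
                                   ctx$pre$ev_nf_lvl[[k]])] * (1 - cf[[k]])
    }
    i <- e$ev_f_by_event[[k]]
    if (length(i)) {
      pe[i] <- pm_small[[k]][cbind(ctx$pre$ev_f_combo[[k]],
                                   ctx$pre$ev_f_lvl[[k]])] * cf[[k]]
    }
  }
  pe[e$idx$dm_inc] <- ctx$inc_m[cbind(ctx$pre$dm_inc_grp, t)]
  pe[e$idx$dm_reinc] <- ctx$inc_m[cbind(ctx$pre$dm_reinc_grp, t)]
  pe[e$idx$dm_rem] <- ctx$rem_m[t]
  pe[e$idx$conv] <- if (is.finite(ctx$s0) && t > ctx$s0) ctx$conv_m else 0
  pe[e$idx$die_bg] <- qm
  pe[e$idx$die_x] <- qm * ctx$pre$die_x_mm1
  if (any(pe < 0)) {
    stop("negative pre-normalisation transition mass at cycle ", t,
         " (mis-specified inputs, e.g. a mortality multiplier below 1)")
  }

  ns <- e$nonstay
  # every living state has a background-death edge, so the grouping is
  # complete and rowsum's sorted groups align with 1..nL
  ex <- as.vector(rowsum(pe[ns], e$gfrom[ns]))
  over <- ex > 1
  n_renorm <- sum(over)
  if (n_renorm) {
    scale <- ifelse(over, 1 / ex, 1)
    pe[ns] <- pe[ns] * scale[e$gfrom[ns]]
    ex <- pmin(ex, 1)
  }
  pe[e$stay_by_living] <- 1 - ex

  ktia <- match("tia", .cvd_events)
  p_tia <- pm_small[[ktia]][cbind(ctx$pre$tia_combo, ctx$pre$tia_lvl)]

  list(pe = pe, p_tia = p_tia, n_renorm = n_renorm)
}

#' Build the transition matrix of one cycle
#'
#' Explicit dense row-stochastic matrix over the full state space at cycle
#' `t`, assembled from independent per-event monthly probabilities with
#' row renormalisation if the total exit mass exceeds 1 (competing-risk
#' convention). Death rows are identity. In the surgery cycle
#' (`t == surgery_month` of a surgery-arm context) the comparator-track
#' rows route through 30-day mortality and the complication split.
#'
#' @param ctx a [model_context()].
#' @param t cycle index (`1 <= t <= horizon`).
#' @return an `n x n` matrix with rows summing to 1.
#' @export
build_transition_matrix <- function(ctx, t) {
  stopifnot(t >= 1, t <= ctx$horizon)
  n <- ctx$space$n
  e <- ctx$edges
  M <- matrix(0, n, n, dimnames = list(ctx$space$states$name,
                                       ctx$space$states$name))
  cp <- cycle_probs(ctx, t)
  key <- (e$to - 1L) * n + e$from
  agg <- rowsum(cp$pe, key)
  M[as.integer(rownames(agg))] <- agg
  for (i in e$i_dead) M[i, i] <- 1
  if (is.finite(ctx$s0) && t == ctx$s0) {
    # surgery cycle: instantaneous routing composed with the normal month
    p30 <- ctx$outcomes$thirty_day_mortality
    pcomp <- ctx$outcomes$complication
    R <- diag(n)
    R[ctx$cmm_living, ] <- 0
    R[cbind(ctx$cmm_living, ctx$map_surg)] <- (1 - p30) * (1 - pcomp)
    R[cbind(ctx$cmm_living, ctx$map_comp)] <- (1 - p30) * pcomp
    ii <- cbind(ctx$cmm_living, rep(e$i_dead_other, length(ctx$cmm_living)))
    R[ii] <- R[ii] + p30
    M <- R %*% M
    dimnames(M) <- list(ctx$space$states$name, ctx$space$states$name)
  }
  M
}

#' Run one cohort arm
#'
#' Propagates the initial occupancy through the per-cycle transition
#' structure, recording the occupancy trace and the per-cycle event flows
#' (first incidences per cardiovascular event, fatal events, transient
#' ischemic attacks, diabetes onset/remission, conversions, surgery).
#'
#' @param ctx a [model_context()].
#' @return an object of class `baricea_run`: list with `occupancy`
#'   (`(horizon + 1) x n` matrix, row `t + 1` = occupancy after cycle
#'   `t`), `flows` (list of per-cycle flow vectors/matrices), and `ctx`.
#' @export
simulate_arm <- function(ctx) {
  e <- ctx$edges
  n <- ctx$space$n
  H <- ctx$horizon
  v <- ctx$v0
  occ <- matrix(0, H + 1L, n, dimnames = list(NULL, ctx$space$states$name))
  occ[1L, ] <- v
  nEv <- length(.cvd_events)
  ev_nf <- matrix(0, H, nEv, dimnames = list(NULL, .cvd_events))
  ev_f <- matrix(0, H, nEv, dimnames = list(NULL, .cvd_events))
  tia <- dm_inc <- dm_reinc <- rem <- conv <- surgery <- sae <- numeric(H)
  n_renorm <- integer(H)
  i_dead <- e$i_dead

  for (t in seq_len(H)) {
    if (is.finite(ctx$s0) && t == ctx$s0) {
      # the operation itself: instantaneous routing through 30-day
      # mortality and the complication split at the start of the cycle;
      # the normal month (background mortality, events) then follows
      p30 <- ctx$outcomes$thirty_day_mortality
      pcomp <- ctx$outcomes$complication
      vcm <- v[ctx$cmm_living]
      tot <- sum(vcm)
      vn <- v
      vn[ctx$cmm_living] <- 0
      vn[ctx$map_surg] <- vn[ctx$map_surg] + vcm * (1 - p30) * (1 - pcomp)
      vn[ctx$map_comp] <- vn[ctx$map_comp] + vcm * (1 - p30) * pcomp
      vn[e$i_dead_other] <- vn[e$i_dead_other] + tot * p30
      surgery[t] <- tot
      sae[t] <- tot * ctx$outcomes$severe_adverse_event
      v <- vn
    }
    cp <- cycle_probs(ctx, t)
    flows <- v[e$from] * cp$pe
    vn <- numeric(n)
    vn[e$tou] <- rowsum(flows, e$gto)
    vn[i_dead] <- vn[i_dead] + v[i_dead]
    for (k in seq_len(nEv)) {
      ev_nf[t, k] <- sum(flows[e$ev_nf_by_event[[k]]])
      ev_f[t, k] <- sum(flows[e$ev_f_by_event[[k]]])
    }
    tia[t] <- sum(v[e$living] * cp$p_tia)
    dm_inc[t] <- sum(flows[e$idx$dm_inc])
    dm_reinc[t] <- sum(flows[e$idx$dm_reinc])
    rem[t] <- sum(flows[e$idx$dm_rem])
    conv[t] <- sum(flows[e$idx$conv])
    n_renorm[t] <- cp$n_renorm
    v <- vn
    if (abs(sum(v) - 1) > 1e-9) {
      stop("occupancy mass not conserved at cycle ", t)
    }
    occ[t + 1L, ] <- v
  }

  structure(list(
    occupancy = occ,
    flows = list(ev_nf = ev_nf, ev_f = ev_f, tia = tia, dm_inc = dm_inc,
                 dm_reinc = dm_reinc, remission = rem, conversion = conv,
                 surgery = surgery, sae = sae, n_renorm = n_renorm),
    ctx = ctx
  ), class = "baricea_run")
}

#' Run a cohort with an explicit matrix provider
#'
#' Reference engine: multiplies the occupancy vector by the matrix
#' returned by `matrix_provider(t)` each cycle, checking row
#' stochasticity and mass conservation. Useful for toy models and as the
#' independent cross-check of [simulate_arm()].
#'
#' @param space a `baricea_state_space`, or any object with `n` and a
#'   `states$alive` logical (for toys, see [toy_state_space()]).
#' @param initial initial occupancy vector (sums to 1).
#' @param horizon_months number of cycles.
#' @param matrix_provider function of the cycle index returning an
#'   `n x n` transition matrix.
#' @return a `baricea_trace`: list with `occupancy` and `space`.
#' @export
run_cohort <- function(space, initial, horizon_months, matrix_provider) {
  n <- space$n
  stopifnot(length(initial) == n)
  if (abs(sum(initial) - 1) > 1e-9) stop("initial occupancy must sum to 1")
  stopifnot(horizon_months >= 1)
  v <- as.numeric(initial)
  occ <- matrix(0, horizon_months + 1L, n)
  occ[1L, ] <- v
  for (t in seq_len(horizon_months)) {
    M <- matrix_provider(t)
    if (any(M < -1e-12) || any(abs(rowSums(M) - 1) > 1e-8)) {
      stop("non-stochastic transition matrix at cycle ", t)
    }
    v <- as.vector(v %*% M)
    if (abs(sum(v) - 1) > 1e-9) stop("occupancy mass lost at cycle ", t)
    occ[t + 1L, ] <- v
  }
  structure(list(occupancy = occ, space = space), class = "baricea_trace")
}

#' Minimal state-space stub for toy models
#'
#' @param names state names.
#' @param alive logical vector marking living states.
#' @return a list usable as the `space` argument of [run_cohort()].
#' @export
toy_state_space <- function(names, alive) {
  stopifnot(length(names) == length(alive))
  list(n = length(names),
       states = data.frame(name = names, alive = alive,
                           stringsAsFactors = FALSE))
}

# internal: occupancy matrix and living mask from a run or trace
occupancy_of <- function(x) {
  if (inherits(x, "baricea_run")) {
    list(occ = x$occupancy, alive = x$ctx$space$states$alive)
  } else if (inherits(x, "baricea_trace")) {
    list(occ = x$occupancy, alive = x$space$states$alive)
  } else stop("expected a baricea_run or baricea_trace")
}

#' Life years accrued over a trace
#'
#' Sum over cycles of the living occupancy times 1/12 year, discounted
#' per `discount`.
#'
#' @param trace a `baricea_run` or `baricea_trace`.
#' @param discount a [discount_spec()]; use rate 0 for undiscounted life
#'   years.
#' @param horizon optional truncation (cycles); default, the full trace.
#' @return life years (scalar).
#' @export
life_years <- function(trace, discount = discount_spec(0), horizon = NULL) {
  o <- occupancy_of(trace)
  H <- nrow(o$occ) - 1L
  if (!is.null(horizon)) H <- min(H, as.integer(horizon))
  living <- rowSums(o$occ[1L + seq_len(H), o$alive, drop = FALSE])
  discount_series(living / 12, discount)
}

#' Export an occupancy trace as a delimited table
#'
#' @param run a `baricea_run` or `baricea_trace`.
#' @param path optional TSV path.
#' @return data frame: one row per cycle, one column per state (plus
#'   cumulative event counters for full runs).
#' @export
export_trace <- function(run, path = NULL) {
  o <- occupancy_of(run)
  df <- data.frame(cycle = 0:(nrow(o$occ) - 1L), o$occ, check.names = FALSE)
  if (inherits(run, "baricea_run")) {
    f <- run$flows
    cum0 <- function(x) cumsum(c(0, x))
    for (ev in .cvd_events) {
      df[[paste0("cum_", ev)]] <- cum0(f$ev_nf[, ev] + f$ev_f[, ev])
    }
    df$cum_tia <- cum0(f$tia)
    df$cum_t2d_onset <- cum0(f$dm_inc)
    df$cum_remission <- cum0(f$remission)
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
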