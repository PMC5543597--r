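# Health-state enumeration.
#
# A living state is the combination of
#   * a treatment track: CMM (conventional management), SURG (post-surgery,
#     no complication), COMP (post-surgery with complication), CONV
#     (post-conversion from adjustable banding to bypass);
#   * a diabetes status: ND (none), T2D (established), REM (in remission
#     after surgery);
#   * a set of established cardiovascular conditions (capped), where a
#     stroke carries a month counter implementing the year-1 and year-2
#     tunnel states (forced monthly progression, chronic after 24 months).
# Death is split into a cardiovascular and an other-cause absorbing state.
# Transient ischemic attack is an event, not a state (one-time cost and
# temporary disutility).

.space_cache <- new.env(parent = emptyenv())

#' Configuration of the model state space
#'
#' @param conditions cardiovascular conditions to track as states; any
#'   subset of `"angina"`, `"mi"`, `"stroke"`, `"hf"`, `"pad"`.
#' @param diabetes include diabetes statuses (T2D, remission)?
#' @param conversion include the post-conversion track?
#' @param cvd_cap maximum number of concurrent cardiovascular conditions
#'   (default 2; incident events beyond the cap are suppressed).
#' @param stroke_tunnel_years number of one-year stroke tunnels with
#'   distinct annual costs before the chronic post-stroke state.
#' @param max_states guard on the enumeration size.
#' @return a list of class `baricea_space_config`.
#' @export
state_space_config <- function(conditions = c("angina", "mi", "stroke",
                                              "hf", "pad"),
                               diabetes = TRUE, conversion = TRUE,
                               cvd_cap = 2L, stroke_tunnel_years = 2L,
                               max_states = 5000L) {
  if (length(conditions)) {
    conditions <- match.arg(conditions, .cvd_conditions, several.ok = TRUE)
  }
  structure(list(conditions = conditions, diabetes = isTRUE(diabetes),
                 conversion = isTRUE(conversion),
                 cvd_cap = as.integer(cvd_cap),
                 stroke_tunnel_years = as.integer(stroke_tunnel_years),
                 max_states = as.integer(max_states)),
            class = "baricea_space_config")
}

#' Enumerate the model state space
#'
#' Deterministic enumeration (stable ordering across runs): tracks x
#' diabetes statuses x condition sets (subsets of the enabled conditions
#' up to `cvd_cap`, with a monthly phase counter for stroke), followed by
#' the absorbing death states.
#'
#' @param config a [state_space_config()].
#' @return object of class `baricea_state_space`: list with `states` (a
#'   data frame with one row per state: `name`, `track`, `dm`, `conds`,
#'   `st_phase`, `alive`, `dead_type`), `config`, the chronic-phase index
#'   `chronic_phase`, and a name-keyed index.
#' @export
build_state_space <- function(config = state_space_config()) {
  stopifnot(inherits(config, "baricea_space_config"))
  sig <- paste("space", paste(config$conditions, collapse = ","),
               config$diabetes, config$conversion, config$cvd_cap,
               config$stroke_tunnel_years, config$max_states, sep = "|")
  cached <- get0(sig, envir = .space_cache)
  if (!is.null(cached)) return(cached)
  conds <- config$conditions
  tracks <- c("CMM", "SURG", "COMP", if (config$conversion) "CONV")
  dms <- if (config$diabetes) c("ND", "T2D", "REM") else "ND"
  tun <- 12L * config$stroke_tunnel_years
  chronic <- tun + 1L

  sets <- list(character(0))
  if (length(conds)) {
    for (k in seq_len(min(config$cvd_cap, length(conds)))) {
      cmb <- utils::combn(conds, k, simplify = FALSE)
      sets <- c(sets, cmb)
    }
  }

  rows <- list()
  for (track in tracks) for (dm in dms) for (s in sets) {
    phases <- if ("stroke" %in% s) seq_len(chronic) else 0L
    for (ph in phases) {
      key <- paste(sort(s), collapse = "+")
      lab <- if (!nzchar(key)) "-" else if (ph == 0L) key else if (ph <= tun) {
        sprintf("%s[m%d]", key, ph)
      } else sprintf("%s[chronic]", key)
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(track, dm, lab, sep = "|"), track = track, dm = dm,
        conds = key, st_phase = ph, alive = TRUE, dead_type = "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(conds)) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = "dead_cvd", track = "", dm = "", conds = "", st_phase = 0L,
      alive = FALSE, dead_type = "cvd", stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    name = "dead_other", track = "", dm = "", conds = "", st_phase = 0L,
    alive = FALSE, dead_type = "other", stringsAsFactors = FALSE)

  states <- do.call(rbind, rows)
  if (nrow(states) > config$max_states) {
    stop(sprintf(
      "state space has %d states, exceeding the configured cap of %d; %s",
      nrow(states), config$max_states,
      "reduce the condition set or cvd_cap"))
  }
  index <- seq_len(nrow(states))
  names(index) <- with(states, paste(track, dm, conds, st_phase, sep = "|"))

  out <- structure(list(states = states, config = config,
                        chronic_phase = chronic, tunnel_months = tun,
                        index = index, n = nrow(states)),
                   class = "baricea_state_space")
  assign(sig, out, envir = .space_cache)
  out
}

#' @export
print.baricea_state_space <- function(x, ...) {
  cat(sprintf("<baricea state space: %d states (%d living, %d absorbing)>\n",
              x$n, sum(x$states$alive), sum(!x$states$alive)))
  invisible(x)
}

# internal: look up a state id by attributes (track/dm/conds-key/phase)
state_id <- function(space, track, dm, conds_key, phase) {
  i <- space$index[[paste(track, dm, conds_key, phase, sep = "|")]]
  if (is.null(i)) stop("no such state: ",
                       paste(track, dm, conds_key, phase, sep = "|"))
  i
}

# internal: split a conds key into a character vector
split_conds <- function(key) {
  if (!nzchar(key)) character(0) else strsplit(key, "+", fixed = TRUE)[[1]]
}
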