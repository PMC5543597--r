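# Synthetic background life table.
#
# The model needs age- and sex-specific all-cause mortality with the
# fraction attributable to ischemic heart disease (IHD), which is
# subtracted before use as background mortality because the model
# generates coronary deaths explicitly. National period life tables are
# not shipped; this generator emulates one with a Gompertz-Makeham hazard
# h(age) = a + b * c^age (female baseline; the male hazard is the female
# hazard times sex_ratio). The IHD fraction rises sigmoidally with age and
# saturates at ihd_peak_fraction.

#' Generate a synthetic period life table
#'
#' @param makeham_a age-independent (background) annual hazard component.
#' @param gompertz_b scale of the exponential senescent hazard component.
#' @param gompertz_c annual multiplicative growth of the senescent hazard.
#' @param ihd_peak_fraction asymptotic fraction of all-cause mortality
#'   attributable to ischemic heart disease (in `[0, 1)`).
#' @param sex_ratio male/female hazard ratio (`> 1` gives male excess
#'   mortality at every age).
#' @param max_age closure age: `q(max_age) = 1`.
#' @param seed optional integer; when given, multiplicative lognormal
#'   noise (SD 1% on the log scale) is added to the annual probabilities,
#'   with monotonicity above age 30 restored by a running maximum. The
#'   table is deterministic given parameters and seed.
#' @return a `baricea_life_table`: data frame with columns `age` (0 to
#'   `max_age`), `sex` (`"male"`/`"female"`), `q_all_cause`,
#'   `ihd_fraction`.
#' @export
generate_life_table <- function(makeham_a = 2e-4, gompertz_b = 2.8e-5,
                                gompertz_c = 1.1, ihd_peak_fraction = 0.15,
                                sex_ratio = 1.6, max_age = 110L,
                                seed = NULL) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c > 1,
            ihd_peak_fraction >= 0, ihd_peak_fraction < 1, sex_ratio > 0)
  ages <- 0:max_age
  haz_f <- makeham_a + gompertz_b * gompertz_c^ages
  make_q <- function(h) {
    bad <- which(h > 1 & ages < 100)
    if (length(bad)) {
      stop(sprintf(
        "parameters produce q > 1 at age %d (before age 100)", ages[bad[1]]))
    }
    pmin(h, 1)
  }
  q_f <- make_q(haz_f)
  q_m <- make_q(haz_f * sex_ratio)
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    noise <- function(q) {
      q <- pmin(1, q * exp(stats::rnorm(length(q), 0, 0.01)))
      i30 <- which(ages >= 30)
      q[i30] <- cummax(q[i30])   # keep q non-decreasing above age 30
      q
    }
    q_f <- noise(q_f); q_m <- noise(q_m)
  }
  q_f[length(ages)] <- 1; q_m[length(ages)] <- 1   # closure
  ihd <- ihd_peak_fraction * stats::plogis((ages - 65) / 10)
  tab <- rbind(
    data.frame(age = ages, sex = "female", q_all_cause = q_f,
               ihd_fraction = ihd),
    data.frame(age = ages, sex = "male", q_all_cause = q_m,
               ihd_fraction = ihd)
  )
  structure(tab, class = c("baricea_life_table", "data.frame"))
}

#' Look up annual all-cause mortality
#'
#' @param table a `baricea_life_table`.
#' @param age age in whole years (within the table).
#' @param sex `"male"` or `"female"`.
#' @return annual probability of death.
#' @export
all_cause_mortality <- function(table, age, sex) {
  sex <- match.arg(sex, c("male", "female"))
  i <- which(table$age == as.integer(age) & table$sex == sex)
  if (!length(i)) stop("age ", age, " outside the life table")
  table$q_all_cause[i]
}

#' Cause-deleted background mortality
#'
#' Removes the ischemic-heart-disease share from all-cause mortality:
#' `q * (1 - ihd_fraction)`. The model charges coronary deaths explicitly
#' through event case fatality, so the background must not double-count
#' them.
#'
#' @inheritParams all_cause_mortality
#' @return annual probability of death from non-IHD causes.
#' @export
cause_deleted_mortality <- function(table, age, sex) {
  sex <- match.arg(sex, c("male", "female"))
  i <- which(table$age == as.integer(age) & table$sex == sex)
  if (!length(i)) stop("age ", age, " outside the life table")
  table$q_all_cause[i] * (1 - table$ihd_fraction[i])
}

#' Remaining discrete life expectancy from a life table
#'
#' Discrete expectation `sum_t S(t) + 0.5` where `S` is the survival
#' curve built from the annual probabilities starting at `from_age`.
#'
#' @param table a `baricea_life_table`.
#' @param from_age starting age (default 0, i.e. at birth).
#' @param sex `"male"` or `"female"`.
#' @return expected remaining years of life.
#' @export
life_expectancy <- function(table, from_age = 0, sex = "female") {
  sex <- match.arg(sex, c("male", "female"))
  q <- table$q_all_cause[table$sex == sex & table$age >= from_age]
  if (!length(q)) stop("from_age outside the life table")
  surv <- cumprod(1 - q)
  sum(surv) + 0.5
}

#' Write / read a life table as delimited text
#'
#' Standard period layout: tab-separated columns `age`, `sex`,
#' `q_all_cause`, `ihd_fraction`. A loader is provided so that an actual
#' national table in the same layout can be substituted for the synthetic
#' one.
#'
#' @param table a `baricea_life_table`.
#' @param path file path.
#' @return `write_life_table` returns `path` invisibly; `read_life_table`
#'   returns a `baricea_life_table`.
#' @export
write_life_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("age", "sex", "q_all_cause", "ihd_fraction")
  if (!all(need %in% names(tab))) {
    stop("life table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$q_all_cause < 0 | tab$q_all_cause > 1)) {
    stop("q_all_cause outside [0, 1]")
  }
  if (any(tab$ihd_fraction < 0 | tab$ihd_fraction >= 1)) {
    stop("ihd_fraction outside [0, 1)")
  }
  structure(tab[need], class = c("baricea_life_table", "data.frame"))
}

# internal: life table implied by a parameter set
life_table_from_params <- function(params) {
  generate_life_table(
    makeham_a = param_value(params, "lt_makeham_a"),
    gompertz_b = param_value(params, "lt_gompertz_b"),
    gompertz_c = param_value(params, "lt_gompertz_c"),
    ihd_peak_fraction = param_value(params, "lt_ihd_peak_fraction"),
    sex_ratio = param_value(params, "lt_sex_ratio")
  )
}
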