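# Registry microsimulator: generates individual patient records with known
# generative truth (incidence model, cure-model survival, life-table
# background mortality) plus a brute-force complete-prevalence oracle.

#' Define a site scenario for the simulator
#'
#' A scenario specifies the generative truth for one cancer entity:
#' an incidence model (age dependence on the logit scale, either
#' log-linear or a polynomial supporting early-onset and bimodal shapes,
#' plus additive 10-year birth-cohort effects) and a mixture cure survival
#' model per age-at-diagnosis band (cure fraction `c`, Weibull shape
#' `gamma` and scale `lambda`, with survivor function of the non-cured
#' `exp(-(lambda * t)^gamma)`).
#'
#' @param site site label.
#' @param age_logit numeric coefficients of the age term on the logit
#'   scale: a polynomial in `x = (age - 50) / 50` evaluated as
#'   `sum(age_logit[k] * x^(k-1))`. Length 2 gives a log-linear ("exponential")
#'   age profile; longer vectors give polynomial (bimodal-capable) shapes.
#' @param cohort_logit named numeric vector of additive logit-scale effects
#'   per 10-year birth cohort; names are decade start years (e.g. "1940").
#'   Birth years outside the named range use the nearest decade.
#' @param cure data.frame with columns `age_band` ("0-59", "60-74", "75+"),
#'   `c`, `gamma`, `lambda`.
#' @param a_min minimum age at diagnosis (incidence is zero below it).
#' @param period_drift optional additive per-5-year-period logit shift on
#'   the cure fraction's complement (a crude survival period effect);
#'   default 0 (no drift).
#' @param age_step5 if TRUE, evaluate the age profile at the 5-year group
#'   midpoint (87.5 for 85+) instead of the single age, so that the true
#'   incidence is piecewise constant on the grid the grouped logistic
#'   age-cohort model fits; used in parameter-recovery experiments.
#' @return object of class `site_scenario`.
#' @export
site_scenario <- function(site, age_logit, cohort_logit, cure, a_min = 0,
                          period_drift = 0, age_step5 = FALSE) {
  cure <- as.data.table(cure)
  stopifnot(all(c("age_band", "c", "gamma", "lambda") %in% names(cure)),
            all(cure$c >= 0 & cure$c <= 1), all(cure$gamma > 0),
            all(cure$lambda > 0), a_min >= 0)
  if (is.null(names(cohort_logit))) stop("cohort_logit must be named by decade start year")
  structure(list(site = site, age_logit = age_logit, cohort_logit = cohort_logit,
                 cure = cure, a_min = a_min, period_drift = period_drift,
                 age_step5 = isTRUE(age_step5)),
            class = "site_scenario")
}

# additive cohort effect for a vector of birth years (nearest decade outside range)
scenario_cohort_effect <- function(scenario, birth_year) {
  decades <- as.integer(names(scenario$cohort_logit))
  dec <- 10L * (as.integer(birth_year) %/% 10L)
  dec <- pmin(pmax(dec, min(decades)), max(decades))
  unname(scenario$cohort_logit[as.character(dec)])
}

#' True annual incidence rate of a scenario
#'
#' @param scenario a `site_scenario`.
#' @param age vector of ages.
#' @param birth_year vector of birth years (recycled).
#' @return annual diagnosis probabilities in \[0, 1).
#' @export
scenario_rate <- function(scenario, age, birth_year) {
  n <- max(length(age), length(birth_year))
  age <- rep_len(age, n); birth_year <- rep_len(birth_year, n)
  age_eval <- if (isTRUE(scenario$age_step5))
    ifelse(age >= 85, 87.5, 5 * (age %/% 5) + 2) else age
  x <- (age_eval - 50) / 50
  lp <- rowSums(vapply(seq_along(scenario$age_logit),
                       function(k) scenario$age_logit[k] * x^(k - 1),
                       numeric(n)))
  lp <- lp + scenario_cohort_effect(scenario, birth_year)
  r <- plogis(lp)
  r[age < scenario$a_min] <- 0
  r
}

#' True cause-specific (net) survival of a scenario
#'
#' The mixture cure survivor function `c + (1 - c) * exp(-(lambda t)^gamma)`
#' for the band containing `age_dx`.
#'
#' @param scenario a `site_scenario`.
#' @param t years since diagnosis.
#' @param age_dx age at diagnosis (scalar).
#' @return survival fractions.
#' @export
scenario_net_survival <- function(scenario, t, age_dx) {
  band <- ltfu_age_band(age_dx)
  p <- scenario$cure[age_band == band]
  if (nrow(p) != 1L) stop("no cure parameters for band ", band)
  p$c + (1 - p$c) * exp(-(p$lambda * t)^p$gamma)
}

# mild default cohort drift: +0.02 on the logit per decade, centred on 1940
default_cohort_logit <- function() {
  dec <- seq(1880, 2010, 10)
  setNames(0.02 * (dec - 1940) / 10, dec)
}

#' Shipped site scenarios
#'
#' Four contrasting generative scenarios used throughout the tests:
#' late-onset/low-survival ("pancreas-like"), late-onset/high-survival
#' ("breast-like"), early-onset/high-survival ("testis-like") and a
#' bimodal age profile ("bimodal-like"). The first two use log-linear age
#' incidence so that the exponential logistic age-cohort model is exactly
#' well-specified; the last two use polynomial age terms nested in the
#' degree-6 basis.
#'
#' @return a `site_scenario`.
#' @export
scenario_pancreas_like <- function() {
  site_scenario("pancreas_like",
    age_logit = c(-8.5, 4.5),   # logit = -8.5 + 4.5 * (age-50)/50, late onset
    cohort_logit = default_cohort_logit(),
    cure = data.frame(age_band = c("0-59", "60-74", "75+"),
                      c = c(0.08, 0.05, 0.04),
                      gamma = c(0.9, 0.9, 0.9),
                      lambda = c(0.8, 0.9, 1.0)),
    a_min = 15)
}

#' @rdname scenario_pancreas_like
#' @export
scenario_breast_like <- function() {
  site_scenario("breast_like",
    age_logit = c(-6.8, 3.2),
    cohort_logit = default_cohort_logit(),
    cure = data.frame(age_band = c("0-59", "60-74", "75+"),
                      c = c(0.70, 0.62, 0.55),
                      gamma = c(1.1, 1.1, 1.1),
                      lambda = c(0.22, 0.25, 0.28)),
    a_min = 20)
}

#' @rdname scenario_pancreas_like
#' @export
scenario_testis_like <- function() {
  # quadratic on the logit scale peaking near age 30, early onset
  site_scenario("testis_like",
    age_logit = c(-10.778, -13.889, -17.361),
    cohort_logit = default_cohort_logit(),
    cure = data.frame(age_band = c("0-59", "60-74", "75+"),
                      c = c(0.88, 0.80, 0.70),
                      gamma = c(1.2, 1.2, 1.2),
                      lambda = c(0.5, 0.5, 0.5)),
    a_min = 15)
}

#' @rdname scenario_pancreas_like
#' @export
scenario_bimodal_like <- function() {
  # quartic with maxima near ages 30 and 70
  site_scenario("bimodal_like",
    age_logit = c(-9 - 60 * 0.4^4, 0, 2 * 60 * 0.4^2, 0, -60),
    cohort_logit = default_cohort_logit(),
    cure = data.frame(age_band = c("0-59", "60-74", "75+"),
                      c = c(0.60, 0.50, 0.40),
                      gamma = c(1.0, 1.0, 1.0),
                      lambda = c(0.4, 0.45, 0.5)),
    a_min = 0)
}

#' Gompertz-Makeham default life table
#'
#' Annual survival `exp(-(A + B * exp(theta * age)))`, constant over
#' calendar time, with slightly higher male mortality. Ages 0-99.
#'
#' @param years calendar years to tabulate.
#' @param sexes subset of `c("male", "female")`.
#' @return a `life_table`.
#' @export
default_life_table <- function(years = 1900:2015, sexes = c("male", "female")) {
  ages <- 0:99
  haz <- function(mult) 5e-4 + mult * 3.2e-5 * exp(0.093 * ages)
  rows <- lapply(sexes, function(s) {
    m <- if (s == "male") 1.35 else 1.0
    data.table(sex = s, age = ages, annual_survival = exp(-haz(m)))
  })
  dt <- rbindlist(rows)
  dt <- dt[, .(year = years), by = .(sex, age, annual_survival)]
  life_table(dt[, .(sex, age, year, annual_survival)])
}

#' Simulation configuration
#'
#' @param registration_start first calendar year of registration.
#' @param index_date prevalence index date (default 1 January 2013).
#' @param sim_start first calendar year simulated; must be at least 60
#'   years before the index date so complete prevalence is well defined
#'   (diagnoses before `sim_start` do not exist in the simulated world).
#' @param pop_size total population per calendar year (stationary).
#' @param sexes sexes to simulate.
#' @param ltfu_rate annual exponential loss-to-follow-up hazard; the
#'   default 0.001 keeps the lost proportion under the 2% that registries
#'   typically report.
#' @param life_table optional `life_table` override (default
#'   [default_life_table()]).
#' @param seed integer random seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(registration_start, index_date = as.Date("2013-01-01"),
                       sim_start = NULL, pop_size = 2e6,
                       sexes = c("male", "female"), ltfu_rate = 0.001,
                       life_table = NULL, seed) {
  index_date <- as.Date(index_date)
  index_year <- as.integer(format(index_date, "%Y"))
  if (is.null(sim_start)) sim_start <- index_year - 70L
  if (sim_start > registration_start) stop("sim_start must not be after registration_start")
  if (registration_start >= index_year) stop("registration must start before the index date")
  if (index_year - sim_start < 60)
    stop("sim_start must be at least 60 years before the index date")
  if (missing(seed)) stop("a seed is mandatory for simulation runs")
  structure(list(registration_start = as.integer(registration_start),
                 index_date = index_date, index_year = index_year,
                 sim_start = as.integer(sim_start), pop_size = pop_size,
                 sexes = sexes, ltfu_rate = ltfu_rate,
                 life_table = life_table, seed = as.integer(seed)),
            class = "sim_config")
}

# Stationary age structure consistent with the life table: weights
# proportional to the survivorship l(a) (zero growth, zero migration).
# This is the demographic regime the completeness-index convolution
# assumes, so the simulator states it as its world.
population_age_weights <- function(lt, sex) {
  ages <- 0:99
  p <- life_table_lookup(lt, sex, ages, lt$years[1])
  l <- cumprod(c(1, p[-length(p)]))
  l / sum(l)
}

# population table: sex x single-year age x calendar year (constant over time)
build_population <- function(config, lt) {
  ages <- 0:99
  years <- config$sim_start:config$index_year
  dt <- rbindlist(lapply(config$sexes, function(s) {
    w <- population_age_weights(lt, s)
    per_sex <- round(config$pop_size * w / length(config$sexes))
    out <- CJ(age = ages, year = years)
    out[, `:=`(sex = s, count = per_sex[age + 1L])]
    out
  }))
  dt[, .(sex, age, year, count)]
}

#' Expected number of incident cases under a scenario and config
#'
#' The analytic mean of the simulator's binomial draws:
#' `sum over (sex, age, year) of pop(age, year) * rate(age, year - age)`.
#'
#' @param scenario a `site_scenario`.
#' @param config a `sim_config`.
#' @return list with `mean` and `sd` (independent-binomial approximation).
#' @export
expected_incident_cases <- function(scenario, config) {
  lt <- if (is.null(config$life_table)) default_life_table() else config$life_table
  pop <- build_population(config, lt)
  pop <- pop[year < config$index_year]
  pop[, rate := scenario_rate(scenario, age, year - age)]
  list(mean = pop[, sum(count * rate)],
       sd = sqrt(pop[, sum(count * rate * (1 - rate))]))
}

# vectorised time-to-other-cause-death (years since diagnosis, continuous):
# yearly Bernoulli thinning against the life table, uniform timing within the
# failure year; capped at 120 years.
draw_other_cause_time <- function(lt, sex, age_dx, year_dx) {
  n <- length(age_dx)
  t_death <- rep(Inf, n)
  alive <- rep(TRUE, n)
  for (k in 0:119) {
    idx <- which(alive)
    if (!length(idx)) break
    p <- life_table_lookup(lt, sex[idx], age_dx[idx] + k, year_dx[idx] + k)
    died <- runif(length(idx)) > p
    d <- idx[died]
    t_death[d] <- k + runif(length(d))
    alive[d] <- FALSE
  }
  t_death[is.infinite(t_death)] <- 120
  t_death
}

#' Simulate a cancer registry
#'
#' Discrete-time microsimulation on a yearly grid. Incident cases are
#' binomial draws per (sex, age, year) cell of the population against the
#' scenario's true incidence rates; each case receives a cause-specific
#' death time from the mixture cure model (cured patients never die of the
#' disease), an other-cause death time from the life table (independent
#' competing risk, the independence assumption underlying relative
#' survival), and an independent exponential loss-to-follow-up time.
#'
#' All diagnoses since `sim_start` are returned (the full truth), each
#' flagged `in_window` when it falls inside the registration window.
#' `death_date` carries the exact simulated death date even beyond the
#' index date, for the brute-force oracle; `date_end` and `vital_status`
#' describe what the registry would observe up to the index date.
#'
#' @param scenario a `site_scenario`.
#' @param config a `sim_config`.
#' @return list with `records` (patient records plus `death_date`,
#'   `in_window`), `population` (data.table `sex,age,year,count`) and
#'   `life_table`.
#' @export
simulate_registry <- function(scenario, config) {
  stopifnot(inherits(scenario, "site_scenario"), inherits(config, "sim_config"))
  set.seed(config$seed)
  lt <- if (is.null(config$life_table)) default_life_table() else config$life_table
  pop <- build_population(config, lt)
  cells <- pop[year < config$index_year]
  cells[, rate := scenario_rate(scenario, age, year - age)]
  if (any(cells$rate >= 1)) stop("incidence rate >= 1 per person-year")
  cells[, n_cases := rbinom(.N, count, rate)]
  cases <- cells[n_cases > 0, .(sex, age_dx = age, year_dx = year, n_cases)]
  if (nrow(cases) == 0L) {
    rec <- data.table(person_id = character(), sex = character(), site = character(),
                      date_dx = as.Date(character()), age_dx = integer(),
                      vital_status = character(), date_end = as.Date(character()),
                      death_date = as.Date(character()), in_window = logical())
    return(list(records = rec, population = pop, life_table = lt))
  }
  rec <- cases[rep(seq_len(.N), n_cases)][, n_cases := NULL]
  n <- nrow(rec)
  # uniform within-year diagnosis timing
  rec[, date_dx := as.Date(paste0(year_dx, "-01-01")) +
        floor(runif(n, 0, 365))]
  # cause-specific time from the mixture cure model (band-wise parameters)
  rec[, age_band := ltfu_age_band(age_dx)]
  rec[, t_cancer := Inf]
  for (b in unique(rec$age_band)) {
    p <- scenario$cure[age_band == b]
    idx <- which(rec$age_band == b)
    cured <- runif(length(idx)) < p$c
    tt <- rep(Inf, length(idx))
    tt[!cured] <- rweibull(sum(!cured), shape = p$gamma, scale = 1 / p$lambda)
    rec[idx, t_cancer := tt]
  }
  rec[, t_other := draw_other_cause_time(lt, sex, age_dx, year_dx)]
  rec[, t_death := pmin(t_cancer, t_other)]
  rec[, t_lost := rexp(n, rate = config$ltfu_rate)]
  rec[, death_date := date_dx + floor(t_death * 365.25)]
  rec[, t_index := as.numeric(config$index_date - date_dx) / 365.25]
  rec[, lost_date := date_dx + floor(t_lost * 365.25)]
  rec[, vital_status := ifelse(t_death <= pmin(t_lost, t_index), "dead",
                        ifelse(t_lost < t_index, "lost", "alive"))]
  # guard day-resolution rounding: a "lost" end date rounded onto/after the
  # index date is treated as alive at index
  rec[vital_status == "lost" & lost_date >= config$index_date, vital_status := "alive"]
  rec[, date_end := fifelse(vital_status == "dead", death_date,
                            fifelse(vital_status == "lost", lost_date,
                                    rep(config$index_date, .N)))]
  rec[, `:=`(person_id = sprintf("P%07d", seq_len(n)), site = scenario$site,
             in_window = year_dx >= config$registration_start)]
  out <- rec[, .(person_id, sex, site, date_dx, age_dx, vital_status, date_end,
                 death_date, in_window)]
  list(records = out, population = pop, life_table = lt)
}

#' Brute-force complete / limited-duration prevalence oracle
#'
#' Exact enumeration over the full simulated truth: persons diagnosed
#' before the index date whose true death date is on or after it, counted
#' by age group at the prevalence date and completed-year duration since
#' diagnosis. No estimation is involved; this is the reference against
#' which every estimated prevalence is scored.
#'
#' @param records full simulated records with a `death_date` column.
#' @param index_date prevalence index date.
#' @param grouping age-grouping scheme.
#' @param max_duration registration length implied by the records
#'   (defaults to the span back to the earliest diagnosis year).
#' @return a `prevalence_table`.
#' @export
true_prevalence <- function(records, index_date,
                            grouping = c("model_5y_85plus", "empirical_wide"),
                            max_duration = NULL) {
  grouping <- match.arg(grouping)
  rec <- as.data.table(records)
  if (!"death_date" %in% names(rec))
    stop("true_prevalence needs full-truth records with a death_date column")
  index_date <- as.Date(index_date)
  alive <- rec[date_dx < index_date & (is.na(death_date) | death_date >= index_date)]
  if (is.null(max_duration)) {
    max_duration <- if (nrow(rec)) {
      as.integer(format(index_date, "%Y")) -
        min(as.integer(format(rec$date_dx, "%Y")))
    } else 1L
  }
  if (nrow(alive) == 0L) {
    return(prevalence_table(
      data.table(sex = character(), site = character(), age_group = character(),
                 duration = integer(), count = numeric()),
      index_date, "truth", max_duration))
  }
  alive[, duration := duration_at_index(date_dx, index_date)]
  # ages are ages at the start of the diagnosis year, so the age attained
  # at a 1 January index date is age_dx + duration + 1
  alive[, age_group := assign_age_group(age_dx + duration + 1L, grouping)]
  counts <- alive[, .(count = as.numeric(.N)), by = .(sex, site, age_group, duration)]
  prevalence_table(counts, index_date, "truth", max_duration)
}

#' Restrict records to a registration window
#'
#' Drops records diagnosed before the registration start; a pure filter
#' used to emulate shorter registration activity.
#'
#' @param records patient records.
#' @param registration_start calendar year (records from 1 January of that
#'   year onward are kept) or a `Date`.
#' @return filtered data.table.
#' @export
truncate_to_registration <- function(records, registration_start) {
  rec <- as.data.table(records)
  start <- if (inherits(registration_start, "Date")) registration_start
           else as.Date(paste0(registration_start, "-01-01"))
  rec[date_dx >= start]
}
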