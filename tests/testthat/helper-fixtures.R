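# Shared fixtures: small record builders and a reusable flat life table.

INDEX <- as.Date("2013-01-01")

make_record <- function(person_id = "P1", sex = "female", site = "colon",
                        date_dx = as.Date("2005-06-15"), age_dx = 60L,
                        vital_status = "alive", date_end = INDEX) {
  data.frame(person_id = person_id, sex = sex, site = site,
             date_dx = as.Date(date_dx), age_dx = as.integer(age_dx),
             vital_status = vital_status, date_end = as.Date(date_end),
             stringsAsFactors = FALSE)
}

bind_records <- function(...) do.call(rbind, list(...))

# life table with constant annual survival p for both sexes, ages 0-99
flat_life_table <- function(p = 1, years = 1940:2015) {
  grid <- expand.grid(sex = c("male", "female"), age = 0:99, year = years,
                      stringsAsFactors = FALSE)
  grid$annual_survival <- p
  life_table(grid)
}

# an incidence model holding a constant rate (no age or cohort dependence)
constant_incidence_model <- function(rate = 1e-4) {
  structure(list(age_form = "exponential",
                 age_coef = setNames(c(qlogis(rate), 0),
                                     c("(Intercept)", "I(x^1)")),
                 cohort_levels = 1950L,
                 cohort_eff = c("1950" = 0),
                 center = 50, scale = 50),
            class = "incidence_model")
}

# incidence model carrying a site_scenario's exact generative truth
scenario_incidence_model <- function(sc) {
  dec <- as.integer(names(sc$cohort_logit))
  deg <- length(sc$age_logit) - 1L
  structure(list(age_form = if (deg == 1) "exponential" else "poly6",
                 age_coef = setNames(sc$age_logit,
                                     c("(Intercept)", paste0("I(x^", seq_len(deg), ")"))),
                 cohort_levels = dec,
                 cohort_eff = setNames(unname(sc$cohort_logit), dec),
                 center = 50, scale = 50),
            class = "incidence_model")
}

# registry-schema column subset
reg_cols <- function(records) {
  as.data.frame(records)[, c("person_id", "sex", "site", "date_dx", "age_dx",
                             "vital_status", "date_end")]
}

# simulate + first-primary filter + truncate, returning analysis-ready records
sim_registry_records <- function(scenario, registration_start, pop_size, seed,
                                 sexes = "female", ...) {
  cfg <- sim_config(registration_start = registration_start, pop_size = pop_size,
                    sexes = sexes, seed = seed, ...)
  sim <- simulate_registry(scenario, cfg)
  rec <- first_primary_filter(reg_cols(
    truncate_to_registration(sim$records, registration_start)))
  list(records = rec, sim = sim, config = cfg)
}

# counting method including the LTFU survival step
count_with_ltfu <- function(records, index_date, registration_start, ...) {
  ltfu <- if (any(records$vital_status == "lost"))
    cohort_life_table_survival(records, index_date) else NULL
  count_limited_duration_prevalence(records, index_date, registration_start,
                                    ltfu_survival = ltfu, ...)
}

# random small truth-bearing record set for oracle-equivalence tests:
# returns full records with death_date (truth) and registry fields at index
random_truth_records <- function(n, seed, p_dead = 0.5) {
  set.seed(seed)
  dx_year <- sample(1985:2012, n, replace = TRUE)
  date_dx <- as.Date(paste0(dx_year, "-01-01")) + sample(0:364, n, replace = TRUE)
  age_dx <- sample(20:85, n, replace = TRUE)
  years_to_death <- rexp(n, rate = p_dead / 4)
  death_date <- date_dx + round(years_to_death * 365.25)
  dead <- death_date < INDEX
  rec <- data.frame(
    person_id = sprintf("P%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    site = sample(c("siteA", "siteB"), n, replace = TRUE),
    date_dx = date_dx, age_dx = age_dx,
    vital_status = ifelse(dead, "dead", "alive"),
    date_end = as.Date(ifelse(dead, death_date, INDEX), origin = "1970-01-01"),
    death_date = death_date,
    stringsAsFactors = FALSE)
  rec
}
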