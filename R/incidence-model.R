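# Logistic age-cohort incidence models: nonparametric 10-year birth-cohort
# effects plus either a log-linear ("exponential") or six-degree-polynomial
# age term on the logit scale; AIC comparison between the two.

AGE_CENTER <- 50
AGE_SCALE <- 50

age_group_mid <- function(label) {
  lo <- suppressWarnings(as.numeric(sub("[-+].*", "", label)))
  hi <- suppressWarnings(as.numeric(sub(".*-", "", label)))
  ifelse(grepl("\\+$", label), lo + 2.5, (lo + hi) / 2)
}

cohort10_of <- function(cohort_year) 10L * (as.integer(round(cohort_year)) %/% 10L)

#' Tabulate incidence by age group and 5-year period
#'
#' Cross-tabulates first-primary records into cases and person-year
#' denominators by sex, site, 5-year age group (85+ terminal) and 5-year
#' period of diagnosis. The birth-cohort index of a cell is the period
#' midpoint year minus the age midpoint. Calendar years outside the
#' registration window contribute neither cases nor person-years; cells
#' with zero person-years are dropped.
#'
#' @param records first-primary-filtered patient records.
#' @param population data.table `sex, age, year, count` (single-year ages).
#' @param registration_start first calendar year of registration.
#' @param last_year last calendar year of incidence (default 2012 for a
#'   1/1/2013 index date).
#' @return data.table of class `incidence_table`: `sex, site, age_group,
#'   age_mid, period, period_mid, cohort, cases, py`.
#' @export
tabulate_incidence <- function(records, population, registration_start,
                               last_year = 2012L) {
  rec <- as.data.table(records)
  pop <- as.data.table(population)
  years <- as.integer(registration_start):as.integer(last_year)
  pop <- pop[year %in% years]
  if (nrow(pop) == 0L) stop("population table does not cover the registration window")
  pop[, age_group := assign_age_group(pmin(age, 85L), "model_5y_85plus")]
  pop[, period := period5(year)]
  denom <- pop[, .(py = sum(count)), by = .(sex, age_group, period)]

  if (nrow(rec)) {
    rec <- rec[, year_dx := as.integer(format(as.Date(date_dx), "%Y"))][
      year_dx %in% years]
  }
  if (nrow(rec)) {
    rec[, age_group := assign_age_group(age_dx, "model_5y_85plus")]
    rec[, period := period5(year_dx)]
    counts <- rec[, .(cases = as.numeric(.N)), by = .(sex, site, age_group, period)]
    sites <- unique(counts$site)
  } else {
    counts <- data.table(sex = character(), site = character(),
                         age_group = character(), period = character(),
                         cases = numeric())
    sites <- character(0)
  }
  grid <- rbindlist(lapply(sites, function(s) copy(denom)[, site := s]))
  if (nrow(grid) == 0L) grid <- copy(denom)[, site := NA_character_][0]
  out <- counts[grid, on = c("sex", "site", "age_group", "period")]
  out[is.na(cases), cases := 0]
  out <- out[py > 0]
  out[, age_mid := age_group_mid(age_group)]
  out[, period_mid := period5_start(period) + 2]
  out[, cohort := period_mid - age_mid]
  if (any(out$cases > out$py)) stop("cases exceed person-years in some cells")
  setorder(out, sex, site, period, age_mid)
  setattr(out, "class", c("incidence_table", class(out)))
  out[]
}

#' Fit a logistic age-cohort model to an incidence table
#'
#' Binomial logistic regression of cases on person-year trials with a
#' parametric age term and nonparametric 10-year birth-cohort indicator
#' effects (reference = earliest cohort). The age variable is the group
#' midpoint centred at 50 and scaled by 50 (so roughly in \[-1, 1\]) before
#' polynomial expansion, for numerical conditioning of the degree-6 terms.
#' `age_form = "exponential"` uses a single linear age term on the logit
#' scale; `"poly6"` uses degrees 1..6.
#'
#' @param table an `incidence_table` for one sex and site.
#' @param age_form `"exponential"` or `"poly6"`.
#' @return object of class `incidence_model`: coefficients, cohort levels
#'   and effects, AIC, log-likelihood, number of parameters, convergence
#'   flag, and the age scaling used.
#' @export
fit_logistic_age_cohort <- function(table, age_form = c("exponential", "poly6")) {
  age_form <- match.arg(age_form)
  dt <- as.data.table(table)
  if (length(unique(dt$sex)) > 1L || length(unique(dt$site)) > 1L)
    stop("fit one (sex, site) stratum at a time")
  dt <- dt[py > 0]
  dt[, x := (age_mid - AGE_CENTER) / AGE_SCALE]
  dt[, cohort10 := cohort10_of(cohort)]
  cohort_levels <- sort(unique(dt$cohort10))
  dt[, cohort10 := factor(cohort10, levels = cohort_levels)]
  deg <- if (age_form == "exponential") 1L else 6L
  rhs <- paste(c(paste0("I(x^", seq_len(deg), ")"),
                 if (length(cohort_levels) > 1L) "cohort10"), collapse = " + ")
  trials <- round(dt$py)
  fml <- stats::as.formula(paste("cbind(cases, trials - cases) ~", rhs))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = dt))
  cf <- coef(fit)
  age_coef <- cf[c("(Intercept)", paste0("I(x^", seq_len(deg), ")"))]
  cohort_eff <- setNames(rep(0, length(cohort_levels)), cohort_levels)
  if (length(cohort_levels) > 1L) {
    nm <- paste0("cohort10", cohort_levels[-1])
    cohort_eff[as.character(cohort_levels[-1])] <- cf[nm]
  }
  if (anyNA(age_coef) || anyNA(cohort_eff))
    warning("aliased coefficients in the age-cohort fit")
  structure(list(age_form = age_form,
                 age_coef = age_coef,
                 cohort_levels = cohort_levels,
                 cohort_eff = cohort_eff,
                 loglik = as.numeric(logLik(fit)),
                 k = attr(logLik(fit), "df"),
                 aic = AIC(fit),
                 deviance = fit$deviance,
                 converged = fit$converged,
                 vcov_diag = diag(stats::vcov(fit)),
                 center = AGE_CENTER, scale = AGE_SCALE),
            class = "incidence_model")
}

#' Compare fitted incidence models by AIC
#'
#' `AIC = -2 loglik + 2k`; the model with the lowest AIC is selected, ties
#' broken toward fewer parameters.
#'
#' @param fits named list of `incidence_model` objects.
#' @return list with `selected` (name), `table` (data.table of AIC,
#'   log-likelihood, parameter counts, sorted by AIC then k).
#' @export
compare_aic <- function(fits) {
  if (length(fits) == 0L) stop("no fits to compare")
  if (is.null(names(fits))) names(fits) <- vapply(fits, `[[`, "", "age_form")
  tab <- data.table(model = names(fits),
                    aic = vapply(fits, `[[`, 0, "aic"),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, function(f) as.numeric(f$k), 0))
  setorder(tab, aic, k)
  list(selected = tab$model[1], table = tab[])
}

#' Predict incidence rates from a fitted age-cohort model
#'
#' Inverse-logit of the fitted linear predictor. Birth cohorts outside the
#' fitted range use the nearest estimated cohort effect (constant
#' extrapolation), which is what the lifelong lookback of complete
#' prevalence requires.
#'
#' @param params an `incidence_model`.
#' @param age ages in years (vector).
#' @param birth_cohort birth years (recycled).
#' @return annual rates in (0, 1).
#' @export
predict_incidence <- function(params, age, birth_cohort) {
  n <- max(length(age), length(birth_cohort))
  age <- rep_len(age, n); birth_cohort <- rep_len(birth_cohort, n)
  x <- (age - params$center) / params$scale
  deg <- length(params$age_coef) - 1L
  lp <- rep(unname(params$age_coef[1]), n)
  for (k in seq_len(deg)) lp <- lp + unname(params$age_coef[k + 1L]) * x^k
  dec <- cohort10_of(birth_cohort)
  dec <- pmin(pmax(dec, min(params$cohort_levels)), max(params$cohort_levels))
  lp <- lp + unname(params$cohort_eff[as.character(dec)])
  plogis(lp)
}
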