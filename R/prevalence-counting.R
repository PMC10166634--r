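# The counting method: limited-duration prevalence at an index date, with
# actuarial life-table survival weights attributed to patients lost to
# follow-up.

LTFU_STRATA <- c("sex", "site", "age_band", "period")

#' Actuarial cohort life-table survival of the patient population
#'
#' Annual conditional survival probabilities of the registry's own patient
#' cohort, computed with the actuarial (life-table) method on annual
#' intervals since diagnosis: patients censored within an interval (lost,
#' or administratively censored at the index date) count as half-exposed.
#' Stratified by sex, site, age-at-diagnosis band (0-59, 60-74, 75+) and
#' 5-year period of diagnosis; coarser poolings (dropping period, then the
#' age band, then pooling sites) are also returned so that sparse strata
#' can fall back deterministically at lookup time.
#'
#' @param records patient records observed up to the index date.
#' @param index_date prevalence index date.
#' @param max_years maximum interval to tabulate (default: longest
#'   follow-up in the data).
#' @return object of class `ltfu_survival`: a list of data.tables, one per
#'   pooling level, each with the stratum columns, `interval` (1-based year
#'   since diagnosis) and `p_cond`.
#' @export
cohort_life_table_survival <- function(records, index_date, max_years = NULL) {
  rec <- validate_records(records, index_date)
  index_date <- as.Date(index_date)
  rec <- rec[date_dx < index_date]
  if (nrow(rec) == 0L) stop("no records before the index date")
  rec[, fu := as.numeric(date_end - date_dx) / 365.25]
  rec[, dead := vital_status == "dead"]
  rec[, age_band := ltfu_age_band(age_dx)]
  rec[, period := period5(as.integer(format(date_dx, "%Y")))]
  if (is.null(max_years)) max_years <- max(1L, ceiling(max(rec$fu)))

  actuarial <- function(dt, by_cols) {
    grid <- rbindlist(lapply(seq_len(max_years), function(j) {
      at_risk <- dt[fu > (j - 1)]
      if (nrow(at_risk) == 0L) return(NULL)
      s <- at_risk[, .(
        n_enter = .N,
        n_death = sum(dead & fu <= j),
        n_withdraw = sum(!dead & fu <= j)
      ), by = by_cols]
      s[, interval := j]
      s
    }))
    if (is.null(grid) || nrow(grid) == 0L) return(data.table())
    grid[, denom := n_enter - n_withdraw / 2]
    grid <- grid[denom > 0]
    grid[, p_cond := pmax(0, 1 - n_death / denom)]
    grid
  }

  levels <- list(
    full        = actuarial(rec, LTFU_STRATA),
    no_period   = actuarial(rec, c("sex", "site", "age_band")),
    no_age      = actuarial(rec, c("sex", "site")),
    sex_only    = actuarial(rec, "sex")
  )
  structure(list(levels = levels, max_years = as.integer(max_years)),
            class = "ltfu_survival")
}

# conditional survival for one (sex, site, band, period) stratum over a set of
# intervals, cascading through the pooling levels; error if nothing matches.
ltfu_lookup <- function(ls, sex_, site_, band_, period_, intervals) {
  stopifnot(inherits(ls, "ltfu_survival"))
  out <- rep(NA_real_, length(intervals))
  pick <- function(dt, cond) {
    hit <- dt[cond][match(intervals, interval), p_cond]
    ifelse(is.na(out), hit, out)
  }
  lv <- ls$levels
  if (nrow(lv$full)) out <- pick(lv$full, lv$full$sex == sex_ & lv$full$site == site_ &
                                   lv$full$age_band == band_ & lv$full$period == period_)
  if (anyNA(out) && nrow(lv$no_period))
    out <- pick(lv$no_period, lv$no_period$sex == sex_ & lv$no_period$site == site_ &
                  lv$no_period$age_band == band_)
  if (anyNA(out) && nrow(lv$no_age))
    out <- pick(lv$no_age, lv$no_age$sex == sex_ & lv$no_age$site == site_)
  if (anyNA(out) && nrow(lv$sex_only))
    out <- pick(lv$sex_only, lv$sex_only$sex == sex_)
  if (anyNA(out))
    stop("no life-table survival available (zero exposure after all fallbacks) for ",
         paste(sex_, site_, band_, period_, collapse = "/"),
         " intervals ", paste(intervals[is.na(out)], collapse = ", "))
  out
}

#' Limited-duration prevalence by the counting method
#'
#' Enumerates, at the index date, the patients known to be alive (weight
#' 1), excludes those known dead (weight 0) and attributes to each patient
#' lost to follow-up the probability of being alive at the index date: the
#' product of the annual conditional survival probabilities of their
#' stratum from the interval after loss up to the index date. Counts are
#' tabulated by age group at the prevalence date and completed-year
#' duration since diagnosis.
#'
#' @param records patient records, already first-primary filtered and
#'   restricted to the registration window.
#' @param index_date prevalence index date.
#' @param registration_start first calendar year of registration (sets
#'   `max_duration`).
#' @param ltfu_survival an `ltfu_survival` object (required only when the
#'   records contain lost patients); pass the output of
#'   [cohort_life_table_survival()].
#' @param grouping age-grouping scheme for the prevalence date.
#' @param registry_id registry label carried on the output.
#' @return a `prevalence_table` (counts may be fractional).
#' @export
count_limited_duration_prevalence <- function(records, index_date,
                                              registration_start,
                                              ltfu_survival = NULL,
                                              grouping = c("model_5y_85plus",
                                                           "empirical_wide"),
                                              registry_id = "registry") {
  grouping <- match.arg(grouping)
  index_date <- as.Date(index_date)
  max_duration <- as.integer(format(index_date, "%Y")) - as.integer(registration_start)
  if (max_duration < 1L) stop("registration must start before the index year")
  rec <- validate_records(records, index_date)
  rec <- rec[date_dx < index_date]
  empty <- prevalence_table(
    data.table(sex = character(), site = character(), age_group = character(),
               duration = integer(), count = numeric()),
    index_date, registry_id, max_duration)
  if (nrow(rec) == 0L) return(empty)
  rec[, duration := duration_at_index(date_dx, index_date)]
  if (any(rec$duration >= max_duration))
    stop("records diagnosed before the registration window; truncate first")
  rec[, contribution := fifelse(vital_status == "alive", 1,
                                fifelse(vital_status == "dead", 0, NA_real_))]
  lost <- which(is.na(rec$contribution))
  if (length(lost)) {
    if (is.null(ltfu_survival))
      stop("records contain lost-to-follow-up patients; supply ltfu_survival")
    for (i in lost) {
      j0 <- completed_years(rec$date_dx[i], rec$date_end[i])
      d <- rec$duration[i]
      if (j0 >= d) { rec[i, contribution := 1]; next }  # lost within final year
      ivals <- (j0 + 1L):d
      p <- ltfu_lookup(ltfu_survival, rec$sex[i], rec$site[i],
                       ltfu_age_band(rec$age_dx[i]),
                       period5(as.integer(format(rec$date_dx[i], "%Y"))), ivals)
      rec[i, contribution := prod(p)]
    }
  }
  rec <- rec[contribution > 0]
  if (nrow(rec) == 0L) return(empty)
  # age at the prevalence date: diagnosis ages are start-of-year ages, so
  # at a 1 January index the attained age is age_dx + duration + 1
  rec[, age_group := assign_age_group(age_dx + duration + 1L, grouping)]
  counts <- rec[, .(count = sum(contribution)), by = .(sex, site, age_group, duration)]
  prevalence_table(counts, index_date, registry_id, max_duration)
}
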