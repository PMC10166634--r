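# Completeness (R-) indexes: model-based (incidence x cure-model survival x
# expected survival convolution), empirical (long-series prevalence ratios)
# and externally supplied tables; plus the complete-prevalence and
# duration-extension estimators built on them.

#' Construct a completeness index
#'
#' R_{i,d} in (0, 1] by sex, site, age group at the prevalence date and
#' duration d: the estimated fraction of complete prevalence captured by
#' d-year limited-duration prevalence. Values must be non-decreasing in d
#' within each cell.
#'
#' @param df data.frame with columns `sex, site, age_group, duration, R`.
#' @param method one of `"empirical"`, `"model"`, `"external"`.
#' @param index_date prevalence index date the index refers to.
#' @param check_monotone warn (rather than fail) on monotonicity
#'   violations, listing the offending cells; used for external tables.
#' @return data.table of class `completeness_index`.
#' @export
completeness_index <- function(df, method = c("model", "empirical", "external"),
                               index_date = as.Date("2013-01-01"),
                               check_monotone = TRUE) {
  method <- match.arg(method)
  dt <- as.data.table(df)
  need <- c("sex", "site", "age_group", "duration", "R")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("completeness index missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(dt$R) | dt$R <= 0 | dt$R > 1))
    stop("R values must lie in (0, 1]")
  setorder(dt, sex, site, age_group, duration)
  if (check_monotone) {
    viol <- dt[, .(bad = any(diff(R) < -1e-9)), by = .(sex, site, age_group)][bad == TRUE]
    if (nrow(viol))
      warning("R not non-decreasing in duration for cells: ",
              paste(viol$sex, viol$site, viol$age_group, sep = "/", collapse = ", "))
  }
  meth <- method
  dt[, method := meth]
  setattr(dt, "index_date", as.Date(index_date))
  setattr(dt, "class", c("completeness_index", class(dt)))
  dt
}

#' Empirical completeness index from long-series prevalence
#'
#' `R_{i,d} = N_{i,<=d} / N_{i,<=max_duration}`: the ratio of observed
#' prevalent cases at duration d to those at the maximum duration,
#' assuming prevalence observed over `max_duration` years (35 in the
#' reference application) is essentially complete. Computed on the wide
#' empirical age grouping (0-29, 5-year, 80+). Cells whose long-series
#' denominator is zero are emitted as missing with a warning.
#'
#' @param prevalence a `prevalence_table` observed to at least
#'   `max_duration`.
#' @param max_duration the duration treated as complete (years).
#' @return a `completeness_index` with `method = "empirical"`.
#' @export
empirical_R <- function(prevalence, max_duration = 35L) {
  stopifnot(inherits(prevalence, "prevalence_table"))
  if (max_duration > attr(prevalence, "max_duration"))
    stop("max_duration exceeds the table's registration length (",
         attr(prevalence, "max_duration"), " years)")
  pt <- regroup_to_empirical(prevalence)
  cum <- cumulative_prevalence(pt, seq_len(max_duration))
  denom <- cum[duration == max_duration, .(sex, site, age_group, denom = count)]
  zero <- denom[denom == 0]
  if (nrow(zero))
    warning("zero long-series prevalence; cells emitted as missing: ",
            paste(zero$sex, zero$site, zero$age_group, sep = "/", collapse = ", "))
  out <- cum[denom[denom > 0], on = c("sex", "site", "age_group")]
  out <- out[count > 0]  # R must be > 0; leading empty durations are missing
  out[, R := pmin(1, count / denom)]
  completeness_index(out[, .(sex, site, age_group, duration, R)],
                     "empirical", attr(prevalence, "index_date"))
}

#' Model-based completeness index
#'
#' Re-implementation of the standard completeness-index computation: for a
#' single age a at the index date, the modelled prevalent mass diagnosed
#' within the past d years is
#' \deqn{P(a, d) = \sum_{t=0}^{\min(d, a - a_{min}) - 1}
#'   I(a-t-1, cohort) \, RS(t + 1/2)}
#' with `I` the fitted annual incidence rate of the person's birth cohort
#' and `RS` the cure-model relative survival of the age-at-diagnosis
#' stratum, evaluated at interval midpoints (t + 1/2) on the yearly grid.
#' The index is `R(a, d) = P(a, d) / P(a, D_max)` with a lifelong lookback
#' `D_max = a - a_min`; cohort effects beyond the fitted range are
#' constantly extrapolated.
#'
#' Expected (general-population) survival does not appear: within the
#' birth cohort currently aged a, the probability of having been diagnosed
#' t years ago and being alive now is proportional to
#' `l(a-t-1) I RS(t) S*(t)`, and the cohort survivorship `l(a-t-1)` times
#' the expected survival from diagnosis to now `S*(t)` equals `l(a)` for
#' every t, so both cancel from the ratio. Setting
#' `use_expected_survival = TRUE` multiplies the mass by `S*(t + 1/2)`
#' instead (the count-based variant, appropriate only together with
#' explicit historical population-at-risk weights; it double-counts
#' other-cause mortality otherwise).
#'
#' @param inc an `incidence_model` for the (sex, site).
#' @param cure data.table of cure parameters with columns `age_band`
#'   ("0-59"/"60-74"/"75+"), `c`, `gamma`, `lambda` (a `converged` column,
#'   if present, must be all TRUE).
#' @param lt a `life_table`.
#' @param sex_ sex label (for the life-table lookup and output key).
#' @param site_ site label for the output key.
#' @param index_date prevalence index date.
#' @param ages single ages at the prevalence date to evaluate.
#' @param durations durations d (years) to report.
#' @param a_min minimum diagnosis age of the site (lookback horizon).
#' @param population optional data.table `sex, age, year, count` giving
#'   population age weights at the index year for grouping.
#' @param use_expected_survival multiply the prevalent mass by expected
#'   survival S* (see Details); default FALSE.
#' @param grouping output age grouping: `"model_5y_85plus"` (default),
#'   `"empirical_wide"`, or `"single"` for ungrouped single-age values
#'   (age_group = the age as character). Group values are
#'   population-weighted means of the single-age R values.
#' @return a `completeness_index` with `method = "model"`.
#' @export
model_based_R <- function(inc, cure, lt, sex_, site_,
                          index_date = as.Date("2013-01-01"),
                          ages = 0:99, durations = c(5, 10, 15, 20, 25, 30, 35),
                          a_min = 0, population = NULL,
                          grouping = c("model_5y_85plus", "empirical_wide",
                                       "single"),
                          use_expected_survival = FALSE) {
  grouping <- match.arg(grouping)
  cure <- as.data.table(cure)
  if ("converged" %in% names(cure) && !all(cure$converged))
    stop("cure-model fit failed for strata: ",
         paste(cure[converged == FALSE, age_band], collapse = ", "))
  index_year <- as.integer(format(as.Date(index_date), "%Y"))
  ages <- ages[ages > a_min]
  if (!length(ages)) stop("no evaluable ages above a_min")
  cure_of <- function(age_dx) {
    band <- ltfu_age_band(age_dx)
    m <- match(band, cure$age_band)
    if (anyNA(m)) {
      fb <- match("all", cure$age_band)  # pooled fallback for sparse bands
      if (is.na(fb))
        stop("missing cure parameters for band(s): ",
             paste(unique(band[is.na(m)]), collapse = ", "))
      m[is.na(m)] <- fb
    }
    cure[m]
  }
  rows <- vector("list", length(ages))
  for (ii in seq_along(ages)) {
    a <- ages[ii]
    Dmax <- a - a_min
    tt <- 0:(Dmax - 1L)
    age_dx <- a - tt - 1L
    year_dx <- index_year - tt - 1L
    cohort <- index_year - a
    I_t <- predict_incidence(inc, age_dx, cohort)
    cp <- cure_of(age_dx)
    RS_t <- cp$c + (1 - cp$c) * exp(-(cp$lambda * (tt + 0.5))^cp$gamma)
    mass <- I_t * RS_t
    if (use_expected_survival) {
      # S*(t + 1/2): t full annual factors from diagnosis, then half of
      # the final attained year's factor
      p_seq <- life_table_lookup(lt, sex_, (a - Dmax):(a - 1L),
                                 (index_year - Dmax):(index_year - 1L))
      logp <- log(p_seq)                 # dx at age a-t-1: last t+1 entries
      crev <- rev(cumsum(rev(logp)))
      mass <- mass * exp(crev[Dmax - tt] - 0.5 * logp[Dmax])
    }
    Pa <- cumsum(mass)                            # P(a, d) for d = 1..Dmax
    if (Pa[Dmax] <= 0) next
    dd <- durations[durations >= 1]
    dcl <- pmin(dd, Dmax)
    R <- Pa[dcl] / Pa[Dmax]
    if (any(R > 1 + 1e-9)) stop("computed R exceeds 1 beyond numerical noise")
    rows[[ii]] <- data.table(age = a, duration = as.integer(dd),
                             R = pmin(R, 1), mass = Pa[Dmax])
  }
  sa <- rbindlist(rows)
  if (nrow(sa) == 0L) stop("no prevalent mass at any requested age")
  if (grouping == "single") {
    out <- sa[, .(sex = sex_, site = site_, age_group = as.character(age),
                  duration, R)]
    return(completeness_index(out, "model", index_date))
  }
  if (!is.null(population)) {
    pop <- as.data.table(population)
    pop <- pop[sex == sex_ & year == index_year, .(age, weight = count)]
    sa <- pop[sa, on = "age"]
    sa[is.na(weight), weight := 1]
  } else sa[, weight := 1]
  sa[, age_group := assign_age_group(age, grouping)]
  # group value: ratio of population-weighted prevalent masses, the
  # aggregation consistent with applying the index to grouped counts
  # (P(a, d) = R(a, d) * mass(a))
  out <- sa[, .(R = sum(weight * R * mass) / sum(weight * mass)),
            by = .(age_group, duration)]
  out[, `:=`(sex = sex_, site = site_)]
  completeness_index(out[, .(sex, site, age_group, duration, R)],
                     "model", index_date)
}

# look up R for given cells; returns NA where absent
index_lookup <- function(index, cells) {
  idx <- as.data.table(index)
  idx[cells, on = c("sex", "site", "age_group", "duration"), R]
}

# coarsen a completeness index from the model scheme to the empirical scheme
# (weighted by nothing: only meaningful via matching tables; used to align
# groupings when the prevalence table is on the wide scheme)
align_index_groups <- function(index, groups) {
  idx <- as.data.table(index)
  if (all(unique(groups) %in% unique(idx$age_group))) return(idx)
  # map model-scheme rows onto empirical-wide labels by simple averaging
  lower <- suppressWarnings(as.integer(sub("[-+].*", "", idx$age_group)))
  if (anyNA(lower)) stop("age groupings of index and prevalence table cannot be aligned")
  idx2 <- copy(idx)
  idx2[, age_group := ifelse(lower < 30, "0-29",
                             ifelse(lower >= 80, "80+", age_group))]
  idx2[, .(R = mean(R)), by = .(sex, site, age_group, duration, method)]
}

#' Estimate complete prevalence from a limited-duration table and an index
#'
#' Complete prevalence per cell is the observed limited-duration count at
#' the table's maximum duration divided by the corresponding R-index:
#' `N_i = N_{i,<=dmax} / R_{i,dmax}`. The estimate is never below the
#' observed count (R <= 1). Age groupings are aligned internally (a
#' model-scheme index is coarsened to the empirical scheme if needed).
#'
#' @param prevalence a `prevalence_table`.
#' @param index a `completeness_index` whose durations cover the table's
#'   `max_duration`.
#' @return data.table `sex, site, age_group, observed, R, complete`.
#' @export
complete_prevalence <- function(prevalence, index) {
  stopifnot(inherits(prevalence, "prevalence_table"),
            inherits(index, "completeness_index"))
  dmax <- attr(prevalence, "max_duration")
  if (!dmax %in% unique(index$duration))
    stop("index does not cover the table's maximum duration (", dmax, " years)")
  obs <- cumulative_prevalence(prevalence, dmax)
  idx <- align_index_groups(index, unique(obs$age_group))
  obs[, R := idx[obs, on = c("sex", "site", "age_group", "duration"), R]]
  bad <- obs[is.na(R) & count > 0]
  if (nrow(bad))
    stop("missing or zero R-index for nonzero cells: ",
         paste(bad$sex, bad$site, bad$age_group, sep = "/", collapse = ", "))
  if (nrow(obs[is.na(R) & count == 0]))
    warning("empty cells with missing R-index kept at 0")
  out <- obs[, .(sex, site, age_group, observed = count, R,
                 complete = fifelse(count == 0, 0, count / R))]
  out[]
}

#' Extend limited-duration prevalence to a longer duration
#'
#' `N_{d2} = N_{d1} / (R_{d1} / R_{d2})`: observed prevalence at the
#' maximum available duration d1, divided by the ratio of the two
#' R-indexes, estimates prevalence at any longer duration d2. With
#' `d1 = d2` this is the identity; with d2 at the complete horizon it
#' reproduces [complete_prevalence()].
#'
#' @param counts data.table `sex, site, age_group, count` of d1-year
#'   prevalence (e.g. from [cumulative_prevalence()]).
#' @param index a `completeness_index` containing both durations.
#' @param d1,d2 durations in years, `d2 >= d1`.
#' @return the input with an added `estimate` column for duration d2.
#' @export
extend_prevalence <- function(counts, index, d1, d2) {
  stopifnot(inherits(index, "completeness_index"), d2 >= d1)
  dt <- copy(as.data.table(counts))
  if (d1 == d2) { dt[, estimate := count]; return(dt[]) }
  idx <- align_index_groups(index, unique(dt$age_group))
  cells1 <- copy(dt)[, duration := as.integer(d1)]
  cells2 <- copy(dt)[, duration := as.integer(d2)]
  R1 <- idx[cells1, on = c("sex", "site", "age_group", "duration"), R]
  R2 <- idx[cells2, on = c("sex", "site", "age_group", "duration"), R]
  bad <- which((is.na(R1) | is.na(R2)) & dt$count > 0)
  if (length(bad))
    stop("R-index missing at duration ", d1, " or ", d2, " for nonzero cells: ",
         paste(dt$sex[bad], dt$site[bad], dt$age_group[bad], sep = "/", collapse = ", "))
  dt[, estimate := fifelse(count == 0, 0, count * R2 / R1)]
  dt[]
}

#' Load an externally supplied completeness-index table
#'
#' Reads a CSV of pre-calculated R-indexes (e.g. indexes distributed with
#' other registry programmes) with columns `sex, site, age_group,
#' duration, R`, validates the (0, 1] range (an error) and monotonicity in
#' duration (a warning listing cells), and returns an index usable
#' interchangeably with internally computed ones.
#'
#' @param path CSV file path.
#' @param index_date index date to stamp on the loaded table.
#' @return a `completeness_index` with `method = "external"`.
#' @export
load_external_index <- function(path, index_date = as.Date("2013-01-01")) {
  dt <- fread(path)
  completeness_index(dt[, .(sex, site, age_group, duration, R)],
                     "external", index_date, check_monotone = TRUE)
}

#' Write a completeness index to CSV
#' @param index a `completeness_index`.
#' @param path file path.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "completeness_index"))
  fwrite(as.data.table(index)[, .(sex, site, age_group, duration, R, method)], path)
  invisible(path)
}
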