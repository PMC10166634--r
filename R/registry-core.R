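# Domain types, grouping conventions, first-primary filtering and tabular I/O.

REGISTRY_COLS <- c("person_id", "sex", "site", "date_dx", "age_dx",
                   "vital_status", "date_end")
SEX_LEVELS <- c("male", "female")
VITAL_LEVELS <- c("alive", "dead", "lost")

#' Completed whole years between two dates
#'
#' Durations throughout the package are measured in completed (floored)
#' years: the number of anniversaries of `from` that have passed strictly
#' up to and including `to`. A diagnosis on the index date itself counts
#' zero completed years (and is not prevalent).
#'
#' @param from,to `Date` vectors (recycled).
#' @return integer vector of completed years (negative if `to < from`).
#' @export
#' @examples
#' completed_years(as.Date("2005-06-15"), as.Date("2013-01-01")) # 7
completed_years <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  lf <- as.POSIXlt(from); lt <- as.POSIXlt(to)
  y <- lt$year - lf$year
  before <- (lt$mon < lf$mon) | (lt$mon == lf$mon & lt$mday < lf$mday)
  as.integer(y - before)
}

#' Duration stratum (whole years since diagnosis) at an index date
#'
#' Completed years between the diagnosis date and the day before the index
#' date. Measuring to the day before the index keeps a diagnosis exactly d
#' years before the index inside the d-year window (stratum d - 1), so a
#' registration window opening 1 January of year Y0 yields strata
#' 0..(index_year - Y0 - 1).
#'
#' @param date_dx diagnosis dates.
#' @param index_date the prevalence index date.
#' @return integer duration strata.
#' @export
duration_at_index <- function(date_dx, index_date) {
  completed_years(date_dx, as.Date(index_date) - 1L)
}

#' Age-group labels under the package's two grouping schemes
#'
#' `model_5y_85plus` is the scheme used for modelled quantities: 5-year
#' groups 0-4, 5-9, ..., 80-84 and a terminal 85+. `empirical_wide` is the
#' scheme used for empirical R-indexes, collapsing the extremes (where
#' observed counts are scarce) to 0-29 and 80+ with 5-year groups between.
#'
#' @param scheme `"model_5y_85plus"` or `"empirical_wide"`.
#' @return character vector of ordered group labels.
#' @export
age_group_levels <- function(scheme = c("model_5y_85plus", "empirical_wide")) {
  scheme <- match.arg(scheme)
  five <- function(lo, hi) paste(seq(lo, hi, 5), seq(lo, hi, 5) + 4, sep = "-")
  switch(scheme,
    model_5y_85plus = c(five(0, 80), "85+"),
    empirical_wide  = c("0-29", five(30, 75), "80+"))
}

#' Assign ages to age groups
#'
#' @param age integer vector of ages in years (>= 0).
#' @inheritParams age_group_levels
#' @return character vector of group labels; every non-negative age maps to
#'   exactly one label.
#' @export
#' @examples
#' assign_age_group(87, "model_5y_85plus") # "85+"
#' assign_age_group(83, "empirical_wide")  # "80+"
assign_age_group <- function(age, scheme = c("model_5y_85plus", "empirical_wide")) {
  scheme <- match.arg(scheme)
  if (any(is.na(age)) || any(age < 0)) stop("ages must be non-negative and non-missing")
  if (scheme == "model_5y_85plus") {
    a <- pmin(age %/% 5L, 17L)  # 17 -> 85+
    lev <- age_group_levels("model_5y_85plus")
    lev[a + 1L]
  } else {
    ifelse(age < 30, "0-29",
           ifelse(age >= 80, "80+",
                  paste((age %/% 5L) * 5L, (age %/% 5L) * 5L + 4L, sep = "-")))
  }
}

# 5-year period of diagnosis label, anchored at 1980 (e.g. "2005-2009").
period5 <- function(year) {
  start <- 1980L + 5L * ((as.integer(year) - 1980L) %/% 5L)
  paste(start, start + 4L, sep = "-")
}

period5_start <- function(label) as.integer(sub("-.*", "", label))

# LTFU / survival age-at-diagnosis bands: 0-59, 60-74, 75+.
ltfu_age_band <- function(age) {
  if (any(age < 0)) stop("ages must be non-negative")
  ifelse(age < 60, "0-59", ifelse(age < 75, "60-74", "75+"))
}

#' Validate a table of patient records
#'
#' Checks the registry schema and its invariants: known sex and vital
#' status codes, `date_end >= date_dx`, non-negative age at diagnosis,
#' and (when an index date is given) that patients lost to follow-up have
#' `date_end` strictly before the prevalence index date.
#'
#' @param records data.frame with columns `person_id, sex, site, date_dx,
#'   age_dx, vital_status, date_end`.
#' @param index_date optional `Date`; enables the lost-before-index check.
#' @return the records as a `data.table` (invisibly validated).
#' @export
validate_records <- function(records, index_date = NULL) {
  rec <- copy(as.data.table(records))  # never mutate the caller's table
  miss <- setdiff(REGISTRY_COLS, names(rec))
  if (length(miss)) stop("missing registry columns: ", paste(miss, collapse = ", "))
  rec[, date_dx := as.Date(date_dx)]
  rec[, date_end := as.Date(date_end)]
  if (anyNA(rec$date_dx) || anyNA(rec$date_end)) stop("unparsable or missing dates")
  bad <- !rec$sex %in% SEX_LEVELS
  if (any(bad)) stop("unknown sex codes in rows: ", paste(which(bad), collapse = ", "))
  bad <- !rec$vital_status %in% VITAL_LEVELS
  if (any(bad)) stop("unknown vital_status codes in rows: ", paste(which(bad), collapse = ", "))
  if (any(rec$age_dx < 0)) stop("negative age_dx")
  bad <- rec$date_end < rec$date_dx
  if (any(bad)) stop("date_end before date_dx in rows: ", paste(which(bad), collapse = ", "))
  if (!is.null(index_date)) {
    bad <- rec$vital_status == "lost" & rec$date_end >= as.Date(index_date)
    if (any(bad))
      stop("records lost to follow-up at/after the index date (inconsistent): rows ",
           paste(which(bad), collapse = ", "))
  }
  rec
}

#' Keep the first primary tumour per person and cancer entity
#'
#' Each person contributes at most one record per site: the earliest
#' diagnosis. Records of the same person at different sites are all
#' retained, so people with multiple primaries at different sites count
#' towards the prevalence of each entity.
#'
#' The result is independent of input row order and the operation is
#' idempotent. Exact duplicate rows collapse to one; two records for the
#' same (person, site, diagnosis date) that disagree on vital data are a
#' data-consistency error.
#'
#' @param records data.frame of patient records (registry schema).
#' @return data.table with one row per (person_id, site).
#' @export
first_primary_filter <- function(records) {
  rec <- as.data.table(records)
  if (nrow(rec) == 0) return(rec)
  rec <- unique(rec)
  setorder(rec, person_id, site, date_dx)
  dup <- rec[, .N, by = .(person_id, site, date_dx)][N > 1L]
  if (nrow(dup) > 0L)
    stop("conflicting duplicate registrations for: ",
         paste(dup$person_id, dup$site, sep = "/", collapse = ", "))
  rec[, head(.SD, 1L), by = .(person_id, site)]
}

# ---- life tables -----------------------------------------------------------

#' Build a life-table object from a long table of annual survival
#'
#' @param df data.frame with columns `sex, age, year, annual_survival`
#'   (annual survival probabilities in (0, 1]).
#' @return object of class `life_table`: a dense array indexed by sex,
#'   single-year age and calendar year. Lookups above the top tabulated age
#'   return the top-age value; calendar years outside the tabulated range
#'   use the nearest tabulated year.
#' @export
life_table <- function(df) {
  dt <- as.data.table(df)
  need <- c("sex", "age", "year", "annual_survival")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("life table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$annual_survival <= 0 | dt$annual_survival > 1))
    stop("life table annual_survival must be in (0, 1]")
  sexes <- sort(unique(dt$sex)); ages <- sort(unique(dt$age)); years <- sort(unique(dt$year))
  if (!identical(ages, ages[1]:ages[length(ages)]))
    stop("life table ages must be contiguous single years")
  arr <- array(NA_real_, dim = c(length(sexes), length(ages), length(years)),
               dimnames = list(sexes, ages, years))
  arr[cbind(match(dt$sex, sexes), match(dt$age, ages), match(dt$year, years))] <-
    dt$annual_survival
  if (anyNA(arr)) stop("life table has holes: every (sex, age, year) cell is required")
  structure(list(surv = arr, sexes = sexes, ages = ages, years = years),
            class = "life_table")
}

#' Look up annual expected survival probabilities
#'
#' @param lt a `life_table`.
#' @param sex,age,year vectors (recycled to a common length).
#' @return numeric vector of annual survival probabilities.
#' @export
life_table_lookup <- function(lt, sex, age, year) {
  stopifnot(inherits(lt, "life_table"))
  n <- max(length(sex), length(age), length(year))
  sex <- rep_len(sex, n); age <- rep_len(age, n); year <- rep_len(year, n)
  si <- match(sex, lt$sexes)
  if (anyNA(si)) stop("sex not present in life table")
  ai <- pmin(pmax(age, lt$ages[1]), lt$ages[length(lt$ages)]) - lt$ages[1] + 1L
  yi <- pmin(pmax(year, lt$years[1]), lt$years[length(lt$years)]) - lt$years[1] + 1L
  lt$surv[cbind(si, ai, yi)]
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read patient records from a registry CSV file
#'
#' Expects a comma-separated UTF-8 file with header
#' `person_id,sex,site,date_dx,age_dx,vital_status,date_end` and ISO-8601
#' dates. Rows that fail to parse are reported with their line numbers.
#'
#' @param path file path.
#' @return data.table of validated patient records.
#' @export
read_registry <- function(path) {
  raw <- fread(path, colClasses = list(character = c("person_id", "sex", "site",
                                                     "date_dx", "date_end")))
  miss <- setdiff(REGISTRY_COLS, names(raw))
  if (length(miss)) stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  d1 <- as.Date(raw$date_dx, format = "%Y-%m-%d")
  d2 <- as.Date(raw$date_end, format = "%Y-%m-%d")
  errs <- character(0)
  if (anyNA(d1)) errs <- c(errs, paste0("unparsable date_dx on data row(s) ",
                                        paste(which(is.na(d1)), collapse = ", ")))
  if (anyNA(d2)) errs <- c(errs, paste0("unparsable date_end on data row(s) ",
                                        paste(which(is.na(d2)), collapse = ", ")))
  bad_sex <- which(!raw$sex %in% SEX_LEVELS)
  if (length(bad_sex)) errs <- c(errs, paste0("unknown sex code on data row(s) ",
                                              paste(bad_sex, collapse = ", ")))
  bad_vs <- which(!raw$vital_status %in% VITAL_LEVELS)
  if (length(bad_vs)) errs <- c(errs, paste0("unknown vital_status on data row(s) ",
                                             paste(bad_vs, collapse = ", ")))
  if (length(errs)) stop(paste(errs, collapse = "; "))
  raw[, date_dx := d1][, date_end := d2]
  validate_records(raw)
}

#' Write patient records to a registry CSV file
#' @param records patient records (registry schema).
#' @param path file path.
#' @export
write_registry <- function(records, path) {
  rec <- as.data.table(records)[, ..REGISTRY_COLS]
  fwrite(rec, path, dateTimeAs = "ISO")
  invisible(path)
}

#' Read a life table from CSV (`sex,age,year,annual_survival`)
#' @param path file path.
#' @return a `life_table`.
#' @export
read_life_table <- function(path) life_table(fread(path))

#' Write a life table to CSV
#' @param lt a `life_table`.
#' @param path file path.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  dt <- as.data.table(expand.grid(sex = lt$sexes, age = lt$ages, year = lt$years,
                                  stringsAsFactors = FALSE))
  dt[, annual_survival := life_table_lookup(lt, sex, age, year)]
  setorder(dt, sex, age, year)
  fwrite(dt, path)
  invisible(path)
}

#' Read a population table from CSV (`sex,age,year,count`)
#'
#' Population denominators by sex, single-year age and calendar year.
#' @param path file path.
#' @return data.table.
#' @export
read_population <- function(path) {
  dt <- fread(path)
  need <- c("sex", "age", "year", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("population table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$count < 0)) stop("population counts must be non-negative")
  dt
}

# ---- prevalence tables -----------------------------------------------------

#' Construct a prevalence table
#'
#' Counts of prevalent cases by sex, site, age group at the prevalence
#' date and completed-year duration since diagnosis, at a fixed index
#' date. Counts may be fractional because patients lost to follow-up
#' contribute survival-probability weights. The d-year limited-duration
#' prevalence N_d is the sum of counts over durations 0..d-1.
#'
#' @param counts data.frame with columns `sex, site, age_group, duration,
#'   count`.
#' @param index_date the prevalence index date.
#' @param registry_id registry label.
#' @param max_duration registration length in years; durations run
#'   0..max_duration-1.
#' @return data.table of class `prevalence_table` with attributes
#'   `index_date`, `registry_id`, `max_duration`.
#' @export
prevalence_table <- function(counts, index_date, registry_id = "registry",
                             max_duration) {
  dt <- as.data.table(counts)
  need <- c("sex", "site", "age_group", "duration", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("prevalence table missing columns: ", paste(miss, collapse = ", "))
  if (any(dt$count < 0)) stop("prevalence counts must be non-negative")
  if (any(dt$duration < 0 | dt$duration >= max_duration))
    stop("durations must lie in 0..max_duration-1")
  setorder(dt, sex, site, age_group, duration)
  setattr(dt, "index_date", as.Date(index_date))
  setattr(dt, "registry_id", registry_id)
  setattr(dt, "max_duration", as.integer(max_duration))
  setattr(dt, "class", c("prevalence_table", class(dt)))
  dt
}

#' Cumulative limited-duration prevalence N_{i,<=d}
#'
#' @param pt a `prevalence_table`.
#' @param durations integer vector of durations d (years); each result row
#'   gives the number of prevalent cases diagnosed within the past d years.
#' @return data.table `sex, site, age_group, duration, count` where
#'   `count` is cumulative.
#' @export
cumulative_prevalence <- function(pt, durations = NULL) {
  stopifnot(inherits(pt, "prevalence_table"))
  if (is.null(durations)) durations <- seq_len(attr(pt, "max_duration"))
  dt <- as.data.table(pt)
  out <- rbindlist(lapply(durations, function(d) {
    s <- dt[duration < d, .(count = sum(count)), by = .(sex, site, age_group)]
    s[, duration := as.integer(d)]
    s
  }))
  cells <- unique(dt[, .(sex, site, age_group)])
  grid <- cells[rep(seq_len(.N), each = length(durations))]
  grid[, duration := rep(as.integer(durations), times = nrow(cells))]
  out <- out[grid, on = c("sex", "site", "age_group", "duration")]
  out[is.na(count), count := 0]
  setorder(out, sex, site, age_group, duration)
  out[]
}

#' Regroup a prevalence table to a different age-grouping scheme
#'
#' Only coarsening from the model scheme (5-year, 85+) to the empirical
#' scheme (0-29, 5-year, 80+) is supported.
#'
#' @param pt a `prevalence_table` on the `model_5y_85plus` scheme.
#' @return a `prevalence_table` on the `empirical_wide` scheme.
#' @export
regroup_to_empirical <- function(pt) {
  stopifnot(inherits(pt, "prevalence_table"))
  dt <- as.data.table(pt)
  lower <- suppressWarnings(as.integer(sub("[-+].*", "", dt$age_group)))
  if (anyNA(lower)) stop("unrecognised age group labels")
  dt[, age_group := ifelse(lower < 30, "0-29", ifelse(lower >= 80, "80+", age_group))]
  out <- dt[, .(count = sum(count)), by = .(sex, site, age_group, duration)]
  prevalence_table(out, attr(pt, "index_date"), attr(pt, "registry_id"),
                   attr(pt, "max_duration"))
}

#' Write / read a prevalence table (CSV with a metadata header line)
#'
#' The first line is a comment `#meta index_date=... registry_id=...
#' max_duration=...` so that the round trip preserves the table's
#' attributes.
#'
#' @param pt a `prevalence_table`.
#' @param path file path.
#' @export
write_prevalence <- function(pt, path) {
  stopifnot(inherits(pt, "prevalence_table"))
  meta <- sprintf("#meta index_date=%s registry_id=%s max_duration=%d",
                  format(attr(pt, "index_date")), attr(pt, "registry_id"),
                  attr(pt, "max_duration"))
  writeLines(meta, path)
  fwrite(as.data.table(pt), path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_prevalence
#' @return `read_prevalence()` returns the `prevalence_table`.
#' @export
read_prevalence <- function(path) {
  meta <- readLines(path, n = 1L)
  if (!startsWith(meta, "#meta")) stop("not a prevalence table file (missing #meta line)")
  kv <- strsplit(trimws(sub("^#meta", "", meta)), " ")[[1]]
  kv <- strsplit(kv, "=")
  vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  dt <- fread(path, skip = 1L)
  prevalence_table(dt, as.Date(vals[["index_date"]]), vals[["registry_id"]],
                   as.integer(vals[["max_duration"]]))
}
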