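test_that("completed_years floors at anniversaries", {
  expect_equal(completed_years(as.Date("2005-06-15"), as.Date("2013-01-01")), 7L)
  expect_equal(completed_years(as.Date("2005-01-01"), as.Date("2013-01-01")), 8L)
  expect_equal(completed_years(as.Date("2012-12-31"), as.Date("2013-01-01")), 0L)
  # duration strata measure to the day before the index
  expect_equal(duration_at_index(as.Date("1978-01-01"), as.Date("2013-01-01")), 34L)
  expect_equal(duration_at_index(as.Date("2005-06-15"), as.Date("2013-01-01")), 7L)
})

test_that("age groups partition every age exactly once under both schemes", {
  ages <- 0:120
  for (scheme in c("model_5y_85plus", "empirical_wide")) {
    labels <- assign_age_group(ages, scheme)
    expect_true(all(labels %in% age_group_levels(scheme)))
    expect_false(anyNA(labels))
    # deterministic single label per age
    expect_identical(labels, assign_age_group(ages, scheme))
  }
  expect_equal(assign_age_group(87, "model_5y_85plus"), "85+")
  expect_equal(assign_age_group(83, "empirical_wide"), "80+")
  expect_equal(assign_age_group(0, "empirical_wide"), "0-29")
  expect_equal(assign_age_group(29, "empirical_wide"), "0-29")
  expect_equal(assign_age_group(30, "empirical_wide"), "30-34")
  expect_error(assign_age_group(-1, "model_5y_85plus"), "non-negative")
})

test_that("first_primary_filter keeps earliest record per person and site", {
  rec <- bind_records(
    make_record("P1", site = "colon", date_dx = "2005-03-01"),
    make_record("P1", site = "colon", date_dx = "2001-07-01"),
    make_record("P1", site = "breast", date_dx = "2003-05-01"))
  out <- first_primary_filter(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out[out$site == "colon", ]$date_dx, as.Date("2001-07-01"))
  expect_true("breast" %in% out$site)
  # empty input is the identity
  expect_equal(nrow(first_primary_filter(rec[0, ])), 0L)
})

test_that("first_primary_filter is idempotent and order-independent", {
  set.seed(1)
  rec <- do.call(rbind, lapply(1:30, function(i)
    make_record(paste0("P", sample(1:8, 1)),
                site = sample(c("colon", "lung"), 1),
                date_dx = as.Date("2000-01-01") + sample(0:4000, 1))))
  out1 <- first_primary_filter(rec)
  out2 <- first_primary_filter(rec[sample(nrow(rec)), ])
  data.table::setorder(out1, person_id, site)
  data.table::setorder(out2, person_id, site)
  expect_equal(as.data.frame(out1), as.data.frame(out2))
  expect_equal(as.data.frame(first_primary_filter(out1)), as.data.frame(out1))
})

test_that("conflicting duplicate registrations are rejected", {
  rec <- bind_records(
    make_record("P1", date_dx = "2001-07-01", vital_status = "alive"),
    make_record("P1", date_dx = "2001-07-01", vital_status = "dead",
                date_end = "2010-01-01"))
  expect_error(first_primary_filter(rec), "conflicting")
})

test_that("registry I/O round-trips and reports malformed rows", {
  rec <- bind_records(
    make_record("P1", date_dx = "2001-07-01"),
    make_record("P2", sex = "male", vital_status = "dead", date_end = "2010-03-04"),
    make_record("P3", vital_status = "lost", date_end = "2011-11-30"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(rec, path)
  back <- read_registry(path)
  expect_equal(as.data.frame(back), rec)

  lines <- readLines(path)
  lines[4] <- sub("2011-11-30", "not-a-date", lines[4])  # data row 3
  writeLines(lines, path)
  expect_error(read_registry(path), "row\\(s\\) 3")
})

test_that("validate_records enforces the schema invariants", {
  expect_error(validate_records(make_record(date_end = "2001-01-01",
                                            date_dx = "2005-01-01")),
               "date_end before date_dx")
  expect_error(validate_records(make_record(vital_status = "unknown")),
               "vital_status")
  expect_error(
    validate_records(make_record(vital_status = "lost", date_end = INDEX),
                     index_date = INDEX),
    "lost")
})

test_that("life tables validate, look up and round-trip", {
  expect_error(flat_life_table(p = 1.2), "\\(0, 1\\]")
  lt <- flat_life_table(p = 0.97, years = 2000:2005)
  expect_equal(life_table_lookup(lt, "female", 50, 2003), 0.97)
  # top-age and year clamping
  expect_equal(life_table_lookup(lt, "male", 130, 2003), 0.97)
  expect_equal(life_table_lookup(lt, "male", 50, 1960), 0.97)
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_equal(life_table_lookup(lt2, "female", 0:99, 2001),
               life_table_lookup(lt, "female", 0:99, 2001))
})

test_that("prevalence tables round-trip with metadata and cumulate correctly", {
  counts <- data.frame(sex = "female", site = "colon",
                       age_group = c("60-64", "60-64", "65-69"),
                       duration = c(0L, 3L, 12L), count = c(2, 1.5, 4))
  pt <- prevalence_table(counts, INDEX, "regX", 20L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_prevalence(pt, path)
  back <- read_prevalence(path)
  expect_equal(as.data.frame(back), as.data.frame(pt))
  expect_equal(attr(back, "registry_id"), "regX")
  expect_equal(attr(back, "max_duration"), 20L)
  expect_equal(attr(back, "index_date"), INDEX)

  cum <- cumulative_prevalence(pt, c(1, 5, 20))
  expect_equal(cum[cum$age_group == "60-64" & cum$duration == 1, ]$count, 2)
  expect_equal(cum[cum$age_group == "60-64" & cum$duration == 5, ]$count, 3.5)
  expect_equal(cum[cum$age_group == "65-69" & cum$duration == 5, ]$count, 0)
  # cumulative counts are non-decreasing in duration
  cumall <- cumulative_prevalence(pt)
  for (g in unique(cumall$age_group))
    expect_true(all(diff(cumall[cumall$age_group == g, ]$count) >= 0))
})

test_that("regrouping to the empirical scheme pools the extremes", {
  counts <- data.frame(sex = "female", site = "colon",
                       age_group = c("0-4", "25-29", "80-84", "85+", "40-44"),
                       duration = 1L, count = c(1, 2, 3, 4, 5))
  pt <- prevalence_table(counts, INDEX, "r", 10L)
  out <- regroup_to_empirical(pt)
  expect_equal(out[out$age_group == "0-29", ]$count, 3)
  expect_equal(out[out$age_group == "80+", ]$count, 7)
  expect_equal(out[out$age_group == "40-44", ]$count, 5)
})
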