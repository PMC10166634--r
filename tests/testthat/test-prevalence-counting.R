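# counting method + actuarial LTFU survival

test_that("actuarial cohort survival matches hand computations", {
  # 10 patients, 2 deaths in year 1, no losses -> year-1 conditional 0.8
  rec <- do.call(rbind, c(
    lapply(1:2, function(i) make_record(paste0("D", i), date_dx = "2005-01-15",
                                        vital_status = "dead",
                                        date_end = "2005-07-15")),
    lapply(1:8, function(i) make_record(paste0("A", i), date_dx = "2005-01-15"))))
  ls <- cohort_life_table_survival(rec, INDEX)
  full <- ls$levels$full
  expect_equal(full[full$interval == 1, ]$p_cond, 0.8)

  # 10 patients, 1 death and 2 losses in year 1 -> denominator 9, survival 8/9
  rec2 <- do.call(rbind, c(
    list(make_record("D1", date_dx = "2005-01-15", vital_status = "dead",
                     date_end = "2005-07-15")),
    lapply(1:2, function(i) make_record(paste0("L", i), date_dx = "2005-01-15",
                                        vital_status = "lost",
                                        date_end = "2005-09-01")),
    lapply(1:7, function(i) make_record(paste0("A", i), date_dx = "2005-01-15"))))
  ls2 <- cohort_life_table_survival(rec2, INDEX)
  expect_equal(ls2$levels$full[interval == 1]$p_cond, 8 / 9)

  # no deaths anywhere -> all probabilities 1
  rec3 <- do.call(rbind, lapply(1:5, function(i)
    make_record(paste0("A", i), date_dx = "2000-06-01")))
  ls3 <- cohort_life_table_survival(rec3, INDEX)
  expect_true(all(ls3$levels$full$p_cond == 1))
})

test_that("counting method handles alive, dead and lost contributions", {
  # alive at index, dx 2005 -> contributes 1 at duration 7
  pt <- count_limited_duration_prevalence(
    make_record("A", date_dx = "2005-04-01", age_dx = 58), INDEX, 1978)
  expect_equal(pt$duration, 7L)
  expect_equal(pt$count, 1)
  expect_equal(pt$age_group, "65-69")  # 58 + 7

  # dead before index contributes 0
  pt0 <- count_limited_duration_prevalence(
    make_record("B", date_dx = "2005-04-01", vital_status = "dead",
                date_end = "2009-01-01"), INDEX, 1978)
  expect_equal(sum(pt0$count), 0)

  # empty input -> empty table
  ptE <- count_limited_duration_prevalence(make_record()[0, ], INDEX, 1978)
  expect_equal(nrow(ptE), 0L)
  expect_equal(attr(ptE, "max_duration"), 35L)
})

test_that("lost patients contribute the product of annual survival", {
  # lost 1/1/2010: three annual intervals to 1/1/2013 at stratum survival 0.9
  lost <- make_record("L", date_dx = "2005-06-15", age_dx = 50,
                      vital_status = "lost", date_end = "2010-01-01")
  # build a company of records that pins the stratum survival at 0.9/year:
  # 10 at risk, 1 death per year among 10, gives 0.9 exactly
  ls <- cohort_life_table_survival(
    do.call(rbind, c(
      list(make_record("D1", date_dx = "2005-06-15", age_dx = 50,
                       vital_status = "dead", date_end = "2006-01-02")),
      lapply(1:9, function(i) make_record(paste0("A", i), date_dx = "2005-06-15",
                                          age_dx = 50)))), INDEX)
  # overwrite with a handmade survival object: constant 0.9 everywhere
  ls$levels$full <- data.table::data.table(
    sex = "female", site = "colon", age_band = "0-59", period = "2005-2009",
    interval = 1:10, p_cond = 0.9)
  ls$levels$no_period <- ls$levels$no_age <- ls$levels$sex_only <-
    data.table::data.table()
  pt <- count_limited_duration_prevalence(lost, INDEX, 1978, ltfu_survival = ls)
  expect_equal(pt$count, 0.9^3, tolerance = 1e-12)
  # lost weight lies in [0, 1] and total <= n
  expect_lte(pt$count, 1)
})

test_that("lost record without survival table is an error; inconsistent dates too", {
  lost <- make_record("L", vital_status = "lost", date_end = "2010-01-01")
  expect_error(count_limited_duration_prevalence(lost, INDEX, 1978), "ltfu_survival")
  badlost <- make_record("L", vital_status = "lost", date_end = "2013-05-01")
  expect_error(count_limited_duration_prevalence(badlost, INDEX, 1978), "lost")
})

test_that("with zero losses the counting method equals the brute-force oracle", {
  for (seed in c(5, 6)) {
    full <- random_truth_records(300, seed = seed)
    pc <- count_limited_duration_prevalence(reg_cols(full), INDEX, 1985)
    tp <- true_prevalence(full, INDEX, max_duration = 28L)
    m <- merge(as.data.frame(pc), as.data.frame(tp),
               by = c("sex", "site", "age_group", "duration"), all = TRUE)
    m[is.na(m)] <- 0
    expect_equal(m$count.x, m$count.y)
    expect_lte(sum(pc$count), 300)
  }
})

test_that("sparse LTFU strata fall back to coarser pooling deterministically", {
  recs <- do.call(rbind, c(
    lapply(1:6, function(i) make_record(paste0("A", i), date_dx = "1995-03-01",
                                        age_dx = 40)),
    list(make_record("D", date_dx = "1995-03-01", age_dx = 40,
                     vital_status = "dead", date_end = "1996-01-01"))))
  ls <- cohort_life_table_survival(recs, INDEX)
  # a period with no data of its own falls back to the pooled estimate
  p <- prevcomplete:::ltfu_lookup(ls, "female", "colon", "0-59", "2010-2014", 1L)
  expect_equal(p, ls$levels$no_period[interval == 1]$p_cond)
  # a stratum absent at every level errors
  expect_error(prevcomplete:::ltfu_lookup(ls, "male", "lung", "75+",
                                          "2010-2014", 1L),
               "zero exposure")
})
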