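# R-index construction (empirical, model-based, external) and the
# complete-prevalence / extension estimators

random_prev_table <- function(seed, max_duration = 35L) {
  set.seed(seed)
  groups <- age_group_levels("empirical_wide")
  counts <- expand.grid(sex = "female", site = "siteX",
                        age_group = groups, duration = 0:(max_duration - 1L),
                        stringsAsFactors = FALSE)
  counts$count <- rpois(nrow(counts), lambda = 5)
  prevalence_table(counts, INDEX, "r", max_duration)
}

test_that("empirical R equals direct division and is 1 at max duration", {
  for (seed in c(1, 2, 3)) {
    pt <- random_prev_table(seed)
    idx <- empirical_R(pt, 35)
    cum <- cumulative_prevalence(pt, 1:35)
    # independent oracle: direct division of cumulative counts
    m <- merge(as.data.frame(idx), as.data.frame(cum),
               by = c("sex", "site", "age_group", "duration"))
    denom <- cum[cum$duration == 35, ]
    m$expected <- m$count / denom$count[match(m$age_group, denom$age_group)]
    expect_equal(m$R, pmin(1, m$expected))
    expect_true(all(idx[idx$duration == 35, ]$R == 1))
    # monotone in d
    for (g in unique(idx$age_group))
      expect_true(all(diff(idx[idx$age_group == g, ]$R) >= -1e-12))
  }
})

test_that("empirical R flags zero denominators and bad max durations", {
  counts <- data.frame(sex = "female", site = "s",
                       age_group = c("40-44", "50-54"), duration = c(2L, 2L),
                       count = c(3, 0))
  pt <- prevalence_table(counts, INDEX, "r", 35L)
  expect_warning(empirical_R(pt, 35), "missing")
  expect_error(empirical_R(pt, 40), "exceeds")
})

test_that("model-based R reduces to d/a in the no-mortality stationary limit", {
  inc <- constant_incidence_model(rate = 1e-4)
  cure <- data.frame(age_band = c("0-59", "60-74", "75+"),
                     c = 1, gamma = 1, lambda = 0.5)
  lt <- flat_life_table(p = 1)
  idx <- model_based_R(inc, cure, lt, "female", "s",
                       ages = c(40, 60, 80), durations = c(5, 15, 35),
                       a_min = 0, grouping = "single")
  for (a in c(40, 60, 80)) for (d in c(5, 15, 35)) {
    got <- idx[idx$age_group == as.character(a) & idx$duration == d, ]$R
    expect_equal(got, d / a, tolerance = 1e-6)
  }
})

test_that("exhausted survivorship forces R to 1 beyond the survival horizon", {
  # no cure and very fast mortality: no survivor passes ~2 years
  inc <- constant_incidence_model(rate = 1e-4)
  cure <- data.frame(age_band = c("0-59", "60-74", "75+"),
                     c = 0, gamma = 3, lambda = 2)
  idx <- model_based_R(inc, cure, flat_life_table(1), "female", "s",
                       ages = c(50, 70), durations = c(3, 5, 15, 35),
                       a_min = 0, grouping = "single")
  expect_true(all(idx[idx$duration >= 3, ]$R > 1 - 1e-9))
})

test_that("model-based R is monotone in d and within (0, 1]", {
  sc <- scenario_breast_like()
  inc <- scenario_incidence_model(sc)
  idx <- model_based_R(inc, sc$cure, default_life_table(), "female", sc$site,
                       durations = 1:35, a_min = sc$a_min)
  expect_true(all(idx$R > 0 & idx$R <= 1))
  for (g in unique(idx$age_group)) {
    sub <- idx[idx$age_group == g, ]
    expect_true(all(diff(sub[order(sub$duration), ]$R) >= -1e-12))
  }
})

test_that("complete_prevalence divides by R at the maximum duration", {
  counts <- data.frame(sex = "female", site = "s", age_group = "60-64",
                       duration = 0:14, count = c(rep(100 / 3, 3), rep(25, 12)))
  counts$count <- 500 / sum(counts$count) * counts$count
  pt <- prevalence_table(counts, INDEX, "r", 15L)
  idx <- completeness_index(
    data.frame(sex = "female", site = "s", age_group = "60-64",
               duration = c(5L, 15L), R = c(0.5, 0.8)), "external", INDEX)
  out <- complete_prevalence(pt, idx)
  expect_equal(out$complete, 625)  # 500 / 0.8
  expect_gte(out$complete, out$observed)

  # R = 1 leaves the observed count unchanged
  idx1 <- completeness_index(
    data.frame(sex = "female", site = "s", age_group = "60-64",
               duration = 15L, R = 1), "external", INDEX)
  expect_equal(complete_prevalence(pt, idx1)$complete, 500)

  # empty cell with missing R -> 0 with warning
  counts0 <- rbind(counts,
                   data.frame(sex = "female", site = "s", age_group = "70-74",
                              duration = 0L, count = 0))
  pt0 <- prevalence_table(counts0, INDEX, "r", 15L)
  expect_warning(out0 <- complete_prevalence(pt0, idx), "kept at 0")
  expect_equal(out0[out0$age_group == "70-74", ]$complete, 0)

  # nonzero cell with missing R -> error
  counts2 <- counts; counts2$age_group <- "40-44"
  pt2 <- prevalence_table(counts2, INDEX, "r", 15L)
  expect_error(complete_prevalence(pt2, idx), "missing or zero R")
})

test_that("extend_prevalence identities hold", {
  counts <- data.frame(sex = "female", site = "s", age_group = "60-64",
                       count = 90)
  idx <- completeness_index(
    data.frame(sex = "female", site = "s", age_group = "60-64",
               duration = c(15L, 20L), R = c(0.9, 0.95)), "external", INDEX)
  # d1 = d2 is the identity
  expect_equal(extend_prevalence(counts, idx, 15, 15)$estimate, 90)
  # hand arithmetic: 90 / (0.9 / 0.95)
  expect_equal(extend_prevalence(counts, idx, 15, 20)$estimate, 95)

  # with d2 at the complete horizon it reproduces complete_prevalence
  pt <- prevalence_table(
    data.frame(sex = "female", site = "s", age_group = "60-64",
               duration = 0:14, count = 6), INDEX, "r", 15L)
  idx2 <- completeness_index(
    data.frame(sex = "female", site = "s", age_group = "60-64",
               duration = c(15L, 60L), R = c(0.72, 1)), "external", INDEX)
  ext <- extend_prevalence(cumulative_prevalence(pt, 15)[, .(sex, site, age_group, count)],
                           idx2, 15, 60)
  cp <- complete_prevalence(pt, idx2)
  expect_equal(ext$estimate, cp$complete)
})

test_that("external index files load, validate and warn on monotonicity", {
  path <- withr::local_tempfile(fileext = ".csv")
  good <- data.frame(sex = "female", site = "s", age_group = "60-64",
                     duration = c(5, 15), R = c(0.6, 0.9))
  utils::write.csv(good, path, row.names = FALSE)
  idx <- load_external_index(path)
  expect_s3_class(idx, "completeness_index")
  expect_equal(unique(idx$method), "external")

  bad <- good; bad$R[1] <- 1.2
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_external_index(path), "\\(0, 1\\]")

  nonmono <- good; nonmono$R <- c(0.9, 0.6)
  utils::write.csv(nonmono, path, row.names = FALSE)
  expect_warning(load_external_index(path), "non-decreasing")
})

test_that("index CSV schema is shared across methods", {
  pt <- random_prev_table(9)
  idx <- empirical_R(pt, 35)
  path <- withr::local_tempfile(fileext = ".csv")
  write_index(idx, path)
  back <- load_external_index(path)
  expect_equal(back$R, idx$R)
})
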