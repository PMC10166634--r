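# Ederer II cohort relative survival and Weibull mixture cure model fitting.

#' Ederer II cohort relative survival
#'
#' Annual-interval cohort relative survival: the ratio of the observed
#' actuarial cumulative survival of the patient cohort to its cumulative
#' expected survival. Expected interval survival follows Ederer II: at the
#' start of each interval, the mean general-population annual survival
#' probability (matched on sex, attained age and calendar year) over the
#' patients still at risk. Standard errors of RS come from the Greenwood
#' variance of the observed curve divided by cumulative expected survival.
#'
#' @param records patient records (censored at the index date; `lost` and
#'   `alive` both count as censored).
#' @param lt a `life_table` providing expected survival.
#' @param strata character vector of stratification columns; defaults to
#'   sex, site and the 0-59/60-74/75+ age-at-diagnosis band (available as
#'   a derived column `age_band`). `"period"` (5-year period of diagnosis)
#'   may be added.
#' @param max_t longest annual interval to estimate.
#' @return data.table of class `survival_curves`: one row per stratum and
#'   interval end `t_int`, with columns `rs`, `se`, `n_risk`. Strata with
#'   no patients are omitted with a warning.
#' @export
relative_survival_ederer2 <- function(records, lt,
                                      strata = c("sex", "site", "age_band"),
                                      max_t = 35L) {
  rec <- validate_records(records)
  if (nrow(rec) == 0L) stop("no records")
  rec[, age_band := ltfu_age_band(age_dx)]
  rec[, period := period5(as.integer(format(date_dx, "%Y")))]
  rec[, fu := as.numeric(date_end - date_dx) / 365.25]
  rec[, dead := vital_status == "dead"]
  rec[, year_dx := as.integer(format(date_dx, "%Y"))]

  one_stratum <- function(dt) {
    out <- vector("list", max_t)
    cum_obs <- 1; cum_exp <- 1; green <- 0
    for (j in seq_len(max_t)) {
      at_risk <- dt[fu > (j - 1)]
      n <- nrow(at_risk)
      if (n == 0L) break
      d <- at_risk[, sum(dead & fu <= j)]
      w <- at_risk[, sum(!dead & fu <= j)]
      denom <- n - w / 2
      if (denom <= 0) break
      p_obs <- max(0, 1 - d / denom)
      # Ederer II: expected interval survival averaged over those at risk
      p_exp <- at_risk[, mean(life_table_lookup(lt, sex, age_dx + j - 1L,
                                                year_dx + j - 1L))]
      cum_obs <- cum_obs * p_obs
      cum_exp <- cum_exp * p_exp
      if (p_obs > 0) green <- green + d / (denom * (denom - d))
      se_obs <- cum_obs * sqrt(green)
      out[[j]] <- data.table(t_int = j, rs = cum_obs / cum_exp,
                             se = se_obs / cum_exp, n_risk = n)
    }
    rbindlist(out)
  }

  curves <- rec[, one_stratum(.SD), by = strata,
                .SDcols = c("fu", "dead", "sex", "age_dx", "year_dx")]
  if (nrow(curves) == 0L) warning("all strata empty; no curves estimated")
  setattr(curves, "class", c("survival_curves", class(curves)))
  setattr(curves, "strata", strata)
  curves
}

#' Predicted relative survival of a Weibull mixture cure model
#'
#' `RS(t) = c + (1 - c) * exp(-(lambda * t)^gamma)`: a fraction `c` of
#' patients is cured (no excess mortality), the remainder's excess-death
#' time is Weibull. `RS(0) = 1`, non-increasing, plateau at `c`.
#'
#' @param params list or one-row data.frame with `c`, `gamma`, `lambda`.
#' @param t years since diagnosis (vector, >= 0).
#' @return survival fractions.
#' @export
predict_relative_survival <- function(params, t) {
  stopifnot(all(t >= 0))
  params$c + (1 - params$c) * exp(-(params$lambda * t)^params$gamma)
}

# weighted least-squares objective on the cumulative RS curve
cure_rss <- function(par, t, rs, w) {
  pred <- par[1] + (1 - par[1]) * exp(-(par[3] * t)^par[2])
  sum(w * (rs - pred)^2)
}

#' Fit a Weibull mixture cure model to a relative-survival curve
#'
#' Weighted nonlinear least squares of `c + (1-c) exp(-(lambda t)^gamma)`
#' to the annual cumulative RS points, weights proportional to inverse
#' variance. Bounded L-BFGS-B optimisation with a multistart grid
#' (`c` in 0.1/0.5/0.9, `gamma` in 0.5/1/2, `lambda` in 0.1/0.5/1);
#' the best converged start wins.
#'
#' @param curve data.frame with columns `t_int` (or `t`), `rs` and
#'   optionally `se` (missing or zero standard errors get the smallest
#'   positive weight's scale).
#' @return object of class `cure_model`: list with `c`, `gamma`, `lambda`,
#'   `converged`, `rss`, `n_points`.
#' @export
fit_weibull_cure <- function(curve) {
  dt <- as.data.table(curve)
  if ("t_int" %in% names(dt)) setnames(dt, "t_int", "t", skip_absent = TRUE)
  if (!all(c("t", "rs") %in% names(dt))) stop("curve needs columns t (or t_int) and rs")
  dt <- dt[!is.na(rs)]
  if (nrow(dt) < 5L) stop("need at least 5 annual RS points to fit a cure model")
  if (!"se" %in% names(dt)) dt[, se := NA_real_]
  v <- dt$se^2
  floorv <- if (any(v > 0, na.rm = TRUE)) min(v[v > 0], na.rm = TRUE) else 1
  v[is.na(v) | v <= 0] <- floorv
  w <- 1 / v
  w <- w / mean(w)
  lower <- c(0, 0.05, 1e-4); upper <- c(1, 10, 10)
  starts <- as.matrix(expand.grid(c = c(0.1, 0.5, 0.9), gamma = c(0.5, 1, 2),
                                  lambda = c(0.1, 0.5, 1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], cure_rss, t = dt$t, rs = dt$rs, w = w,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(c = NA_real_, gamma = NA_real_, lambda = NA_real_,
                          converged = FALSE, rss = NA_real_, n_points = nrow(dt)),
                     class = "cure_model"))
  structure(list(c = unname(best$par[1]), gamma = unname(best$par[2]),
                 lambda = unname(best$par[3]),
                 converged = best$convergence == 0, rss = best$value,
                 n_points = nrow(dt)),
            class = "cure_model")
}

#' Fit cure models by age band with a pooled fallback
#'
#' Fits the Weibull mixture cure model to Ederer II relative survival per
#' age-at-diagnosis band (0-59, 60-74, 75+) and, additionally, to the
#' all-ages pooled curve, returned as band `"all"`. Downstream index
#' construction falls back to the pooled parameters for bands with too few
#' patients to support their own curve.
#'
#' @param records patient records of one (sex, site).
#' @param lt a `life_table`.
#' @param max_t longest annual interval.
#' @param min_points minimum RS points per band.
#' @return data.table with columns `sex, site, age_band, c, gamma, lambda,
#'   converged, rss` including an `"all"` row.
#' @export
fit_cure_by_band <- function(records, lt, max_t = 30L, min_points = 5L) {
  by_band <- suppressWarnings(
    fit_weibull_cure_all(relative_survival_ederer2(records, lt, max_t = max_t),
                         min_points = min_points))
  pooled <- fit_weibull_cure_all(
    relative_survival_ederer2(records, lt, strata = c("sex", "site"),
                              max_t = max_t), min_points = min_points)
  pooled[, age_band := "all"]
  out <- rbind(by_band, pooled, fill = TRUE)
  setcolorder(out, c("sex", "site", "age_band"))
  out[]
}

#' Fit cure models for every stratum of a set of survival curves
#'
#' @param curves a `survival_curves` object.
#' @param min_points strata with fewer RS points are skipped with a
#'   warning, as are strata whose fit fails to converge.
#' @return data.table with the stratum columns plus `c`, `gamma`,
#'   `lambda`, `converged`, `rss`.
#' @export
fit_weibull_cure_all <- function(curves, min_points = 5L) {
  strata <- attr(curves, "strata")
  dt <- as.data.table(curves)
  fits <- dt[, {
    if (.N < min_points) {
      warning("stratum skipped (too few RS points): ",
              paste(unlist(.BY), collapse = "/"), call. = FALSE)
      NULL
    } else {
      f <- fit_weibull_cure(.SD)
      if (!f$converged)
        warning("cure model failed to converge for stratum: ",
                paste(unlist(.BY), collapse = "/"), call. = FALSE)
      data.table(c = f$c, gamma = f$gamma, lambda = f$lambda,
                 converged = f$converged, rss = f$rss)
    }
  }, by = strata]
  fits
}
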