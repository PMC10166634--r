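# Validation statistics: APRD (absolute-value weighted percent relative
# difference, for validating R-indexes by truncation) and PRD (signed, for
# comparing alternative vs standard complete-prevalence estimates).

#' Weighted average absolute percent relative difference (APRD)
#'
#' `APRD = sum_r (|N'_r - N_r| / N_r) w_r x 100`, with weights normalised
#' to sum to 1. Taking absolute values prevents under- and over-estimates
#' from cancelling, so APRD bounds the average discrepancy from
#' observations.
#'
#' @param observed,estimated numeric vectors of per-registry counts,
#'   aligned; every observed count must be positive.
#' @param weights per-registry weights (typically each registry's share of
#'   the site's prevalent cases); normalised internally, so rescaling by a
#'   constant changes nothing.
#' @return APRD in percent (a scalar >= 0).
#' @export
aprd <- function(observed, estimated, weights = NULL) {
  if (length(observed) != length(estimated)) stop("length mismatch")
  if (any(observed <= 0)) stop("observed counts must be positive for APRD")
  if (is.null(weights)) weights <- rep(1, length(observed))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  sum(abs(estimated - observed) / observed * w) * 100
}

#' Signed weighted percent relative difference (PRD)
#'
#' `PRD = sum_r ((N_alt,r - N_std,r) / N_std,r) w_r x 100`. Signed, so
#' under- and over-estimates in different registries can compensate in the
#' average; a negative value means the alternative method underestimates
#' the standard.
#'
#' @param alternative,standard numeric vectors of per-registry complete
#'   prevalence, aligned; standard must be positive.
#' @param weights per-registry weights (typically resident population);
#'   normalised internally.
#' @return PRD in percent (a scalar, any sign).
#' @export
prd <- function(alternative, standard, weights = NULL) {
  if (length(alternative) != length(standard)) stop("length mismatch")
  if (any(standard <= 0)) stop("standard estimates must be positive for PRD")
  if (is.null(weights)) weights <- rep(1, length(alternative))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  sum((alternative - standard) / standard * w) * 100
}

#' Registration-length groups used for method comparison
#'
#' @param years registration lengths in years.
#' @return labels "5-9 y", "10-14 y", "15-19 y", "20-24 y", "25-35 y".
#' @export
registration_length_group <- function(years) {
  ifelse(years < 10, "5-9 y",
  ifelse(years < 15, "10-14 y",
  ifelse(years < 20, "15-19 y",
  ifelse(years < 25, "20-24 y", "25-35 y"))))
}

#' Truncation validation of a completeness index
#'
#' Emulates shorter registration: per registry, observed prevalence is
#' truncated at duration d1 (5, 10 or 15 years), extended to the target
#' duration (20 years) via the ratio `R_{i,d1} / R_{i,20}` of the supplied
#' index, and compared with the registry's actually observed 20-year
#' prevalence. Goodness of fit per (sex, site, d1) is the APRD across
#' registries weighted by each registry's share of observed prevalent
#' cases. Registries with zero observed prevalence for a cell are dropped
#' from that site's APRD with a warning.
#'
#' @param prevalences named list of `prevalence_table`s, one per registry,
#'   each with `max_duration >= target`.
#' @param index a `completeness_index` covering durations
#'   `c(truncations, target)`.
#' @param truncations truncation durations d1.
#' @param target the reference duration (years).
#' @return list with `aprd` (data.table `sex, site, truncation, aprd,
#'   n_registries`) and `detail` (per-registry observed/estimated counts).
#' @export
truncation_validation <- function(prevalences, index, truncations = c(5, 10, 15),
                                  target = 20L) {
  stopifnot(inherits(index, "completeness_index"), length(prevalences) >= 1)
  if (is.null(names(prevalences)))
    names(prevalences) <- paste0("registry", seq_along(prevalences))
  detail <- rbindlist(lapply(names(prevalences), function(r) {
    pt <- prevalences[[r]]
    stopifnot(inherits(pt, "prevalence_table"))
    if (attr(pt, "max_duration") < target)
      stop("registry ", r, " has fewer than ", target, " years of registration")
    obs20 <- cumulative_prevalence(pt, target)
    rbindlist(lapply(truncations, function(d1) {
      if (d1 > target) stop("truncation exceeds the target duration")
      obs_d1 <- cumulative_prevalence(pt, d1)[, .(sex, site, age_group, count)]
      est <- extend_prevalence(obs_d1, index, d1, target)
      cmp <- est[obs20, on = c("sex", "site", "age_group")]
      cmp[is.na(estimate), estimate := 0]
      cmp[, .(registry_id = r, truncation = d1,
              observed = sum(i.count), estimated = sum(estimate)),
          by = .(sex, site)]
    }))
  }))
  ap <- detail[, {
    keep <- observed > 0
    if (!all(keep))
      warning("registries with zero observed prevalence dropped for ",
              paste(unlist(.BY), collapse = "/"), call. = FALSE)
    if (any(keep)) {
      .(aprd = aprd(observed[keep], estimated[keep], weights = observed[keep]),
        n_registries = sum(keep))
    } else NULL
  }, by = .(sex, site, truncation)]
  list(aprd = ap[], detail = detail[])
}

#' Compare complete-prevalence estimates across R-index methods
#'
#' Applies a standard and one or more alternative completeness indexes to
#' each registry's observed prevalence at its maximum duration, then
#' summarises the signed PRD of each alternative against the standard by
#' sex, site and registration-length group, weighting registries by
#' resident population.
#'
#' @param prevalences named list of `prevalence_table`s (one per registry).
#' @param standard the reference `completeness_index`.
#' @param alternatives named list of alternative `completeness_index`es.
#' @param populations named numeric vector of resident population per
#'   registry (defaults to equal weights).
#' @return list with `prd` (data.table `method, sex, site, length_group,
#'   prd, n_registries`) and `detail` (per-registry totals per method).
#' @export
compare_methods <- function(prevalences, standard, alternatives,
                            populations = NULL) {
  stopifnot(inherits(standard, "completeness_index"))
  if (is.null(names(prevalences)))
    names(prevalences) <- paste0("registry", seq_along(prevalences))
  if (is.null(populations))
    populations <- setNames(rep(1, length(prevalences)), names(prevalences))
  totals <- function(pt, index) {
    cp <- complete_prevalence(pt, index)
    cp[, .(complete = sum(complete)), by = .(sex, site)]
  }
  detail <- rbindlist(lapply(names(prevalences), function(r) {
    pt <- prevalences[[r]]
    len <- attr(pt, "max_duration")
    std <- totals(pt, standard)[, method := "standard"]
    alts <- rbindlist(lapply(names(alternatives), function(m)
      totals(pt, alternatives[[m]])[, method := m]))
    out <- rbind(std, alts)
    out[, `:=`(registry_id = r, length_group = registration_length_group(len),
               weight = unname(populations[r]))]
    out
  }))
  std_wide <- detail[method == "standard",
                     .(registry_id, sex, site, standard = complete)]
  cmp <- detail[method != "standard"][std_wide, on = c("registry_id", "sex", "site")]
  cmp <- cmp[!is.na(method) & standard > 0]
  pr <- cmp[, .(prd = prd(complete, standard, weights = weight),
                n_registries = .N),
            by = .(method, sex, site, length_group)]
  list(prd = pr[], detail = detail[])
}
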