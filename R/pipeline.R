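# End-to-end orchestration: simulate registries, count prevalence, fit
# survival and incidence models, build indexes, estimate complete
# prevalence, validate and compare. Deterministic given (config, seed).

#' Build a pipeline run configuration
#'
#' @param scenarios named list of `site_scenario`s (default: the four
#'   shipped contrast scenarios).
#' @param registries data.frame with columns `registry_id` and
#'   `registration_start`; defaults to five registries spanning 10-35
#'   years of registration at the index date.
#' @param estimation_registration_start registration start of the (larger)
#'   estimation registry used to fit the models and the empirical index;
#'   kept disjoint from the validation registries.
#' @param index_date prevalence index date.
#' @param truncations truncation durations for the validation experiment.
#' @param sexes sexes simulated.
#' @param pop_size population per calendar year of each validation
#'   registry; the estimation registry uses `est_pop_factor` times this.
#' @param est_pop_factor size multiplier of the estimation registry.
#' @param seed master seed; per-stage substreams are derived from it.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(scenarios = NULL, registries = NULL,
                            estimation_registration_start = 1978L,
                            index_date = as.Date("2013-01-01"),
                            truncations = c(5, 10, 15),
                            sexes = "female", pop_size = 5e5,
                            est_pop_factor = 8, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(scenarios))
    scenarios <- list(pancreas_like = scenario_pancreas_like(),
                      breast_like = scenario_breast_like(),
                      testis_like = scenario_testis_like(),
                      bimodal_like = scenario_bimodal_like())
  if (is.null(registries))
    registries <- data.frame(
      registry_id = paste0("reg", 1:5),
      registration_start = c(1978L, 1983L, 1988L, 1990L, 1992L))
  index_year <- as.integer(format(as.Date(index_date), "%Y"))
  if (any(registries$registration_start >= index_year))
    stop("index date must fall after every registration start")
  if (any(outer(truncations, index_year - registries$registration_start, `>`)))
    stop("truncation exceeds the registration length of some registry")
  structure(list(scenarios = scenarios, registries = registries,
                 estimation_registration_start = as.integer(estimation_registration_start),
                 index_date = as.Date(index_date), index_year = index_year,
                 truncations = truncations, sexes = sexes,
                 pop_size = pop_size, est_pop_factor = est_pop_factor,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Scenario entries may name the shipped scenarios (`"pancreas_like"`,
#' `"breast_like"`, `"testis_like"`, `"bimodal_like"`).
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  shipped <- list(pancreas_like = scenario_pancreas_like,
                  breast_like = scenario_breast_like,
                  testis_like = scenario_testis_like,
                  bimodal_like = scenario_bimodal_like)
  scen <- NULL
  if (!is.null(cfg$scenarios)) {
    unknown <- setdiff(cfg$scenarios, names(shipped))
    if (length(unknown)) stop("unknown scenario names: ", paste(unknown, collapse = ", "))
    scen <- setNames(lapply(cfg$scenarios, function(s) shipped[[s]]()), cfg$scenarios)
  }
  args <- list(scenarios = scen, seed = cfg$seed)
  for (f in c("estimation_registration_start", "truncations", "sexes",
              "pop_size", "est_pop_factor"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$index_date)) args$index_date <- as.Date(cfg$index_date)
  if (!is.null(cfg$registries)) args$registries <- as.data.frame(cfg$registries)
  do.call(pipeline_config, args)
}

# derived per-stage seeds, all below 2^31 (double arithmetic avoids overflow)
stage_seed <- function(seed, stage, k = 0L) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(stage) * 1009 + k) %% 2000000011)
}

# simulate one registry (all scenarios pooled into one record set)
simulate_one_registry <- function(config, registration_start, pop_size, seed) {
  out <- NULL; pop <- NULL; lt <- NULL
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    cfg <- sim_config(registration_start = registration_start,
                      index_date = config$index_date,
                      sim_start = config$index_year - 70L,
                      pop_size = pop_size, sexes = config$sexes,
                      seed = stage_seed(seed, 1L, i))
    sim <- simulate_registry(sc, cfg)
    sim$records[, person_id := paste0(sc$site, "_", person_id)]
    out <- rbind(out, sim$records)
    pop <- sim$population; lt <- sim$life_table
  }
  list(records = out, population = pop, life_table = lt)
}

#' Run the full pipeline
#'
#' Stages: simulate an estimation registry and a set of validation
#' registries; count limited-duration prevalence; fit Ederer II relative
#' survival + Weibull cure models and logistic age-cohort incidence models
#' on the estimation registry; build model-based and empirical R-indexes;
#' estimate complete prevalence per registry; run the truncation
#' validation (APRD) and the method comparison (PRD). All artifacts are
#' written as CSV plus a JSON manifest; rerunning with the same config and
#' seed reproduces byte-identical outputs.
#'
#' @param config a `run_config` (or path to a JSON config file).
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory results (`indexes`,
#'   `validation`, `comparison`, `complete`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[prevcomplete] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("prevcomplete")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    log_msg("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate ---
  est <- stage("simulate-estimation",
    simulate_one_registry(config, config$estimation_registration_start,
                          config$pop_size * config$est_pop_factor,
                          stage_seed(config$seed, 10L)))
  vals <- stage("simulate-validation", {
    lapply(seq_len(nrow(config$registries)), function(i)
      simulate_one_registry(config, config$registries$registration_start[i],
                            config$pop_size,
                            stage_seed(config$seed, 20L + i)))
  })
  names(vals) <- config$registries$registry_id
  manifest$stages$simulate <- list(
    estimation_records = nrow(est$records),
    validation_records = vapply(vals, function(v) nrow(v$records), 0))

  # --- count prevalence ---
  count_reg <- function(sim, start, id) {
    rec <- truncate_to_registration(sim$records, start)
    rec <- first_primary_filter(rec[, REGISTRY_COLS, with = FALSE])
    ltfu <- if (any(rec$vital_status == "lost"))
      cohort_life_table_survival(rec, config$index_date) else NULL
    count_limited_duration_prevalence(rec, config$index_date, start,
                                      ltfu_survival = ltfu,
                                      registry_id = id)
  }
  est_prev <- stage("count-prevalence",
    count_reg(est, config$estimation_registration_start, "estimation"))
  val_prev <- stage("count-prevalence-validation", {
    setNames(lapply(names(vals), function(i)
      count_reg(vals[[i]], config$registries$registration_start[
        match(i, config$registries$registry_id)], i)), names(vals))
  })
  write_prevalence(est_prev, file.path(out_dir, "prevalence_estimation.csv"))
  for (i in names(val_prev))
    write_prevalence(val_prev[[i]], file.path(out_dir, paste0("prevalence_", i, ".csv")))
  manifest$stages$count <- list(estimation_cells = nrow(est_prev),
                                validation_cells = vapply(val_prev, nrow, 0))

  # --- fit survival and incidence on the estimation registry ---
  est_rec <- first_primary_filter(
    truncate_to_registration(est$records, config$estimation_registration_start)[
      , REGISTRY_COLS, with = FALSE])
  cure_fits <- stage("fit-survival", {
    combos <- unique(est_rec[, .(sex, site)])
    rbindlist(lapply(seq_len(nrow(combos)), function(j)
      fit_cure_by_band(est_rec[sex == combos$sex[j] & site == combos$site[j]],
                       est$life_table,
                       max_t = min(25L, config$index_year -
                                     config$estimation_registration_start))))
  })
  fwrite(cure_fits, file.path(out_dir, "survival_params.csv"))

  inc_tab <- stage("tabulate-incidence",
    tabulate_incidence(est_rec, est$population,
                       config$estimation_registration_start,
                       last_year = config$index_year - 1L))
  inc_fits <- stage("fit-incidence", {
    combos <- unique(as.data.table(inc_tab)[, .(sex, site)])
    fits <- list()
    aic_rows <- list()
    for (j in seq_len(nrow(combos))) {
      sub <- as.data.table(inc_tab)[sex == combos$sex[j] & site == combos$site[j]]
      f_exp <- fit_logistic_age_cohort(sub, "exponential")
      f_p6 <- fit_logistic_age_cohort(sub, "poly6")
      sel <- compare_aic(list(exponential = f_exp, poly6 = f_p6))
      fits[[paste(combos$sex[j], combos$site[j], sep = ".")]] <-
        if (sel$selected == "poly6") f_p6 else f_exp
      aic_rows[[j]] <- data.table(sex = combos$sex[j], site = combos$site[j],
                                  selected = sel$selected,
                                  aic_exponential = sel$table[model == "exponential", aic],
                                  aic_poly6 = sel$table[model == "poly6", aic])
    }
    fwrite(rbindlist(aic_rows), file.path(out_dir, "incidence_aic.csv"))
    fits
  })

  # --- build indexes ---
  model_idx <- stage("build-index-model", {
    rows <- list()
    for (nm in names(inc_fits)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      sx <- parts[1]; st <- parts[2]
      sc <- NULL
      for (s in config$scenarios) if (s$site == st) sc <- s
      cure <- cure_fits[sex == sx & site == st & converged == TRUE,
                        .(age_band, c, gamma, lambda)]
      rows[[nm]] <- model_based_R(inc_fits[[nm]], cure, est$life_table, sx, st,
                                  index_date = config$index_date,
                                  durations = sort(unique(c(config$truncations, 20,
                                                            5:35))),
                                  a_min = sc$a_min, population = est$population,
                                  grouping = "empirical_wide")
    }
    completeness_index(rbindlist(rows), "model", config$index_date)
  })
  emp_idx <- stage("build-index-empirical",
    empirical_R(est_prev, max_duration = min(35L, attr(est_prev, "max_duration"))))
  write_index(model_idx, file.path(out_dir, "index_model.csv"))
  write_index(emp_idx, file.path(out_dir, "index_empirical.csv"))

  # --- complete prevalence per registry (standard index) ---
  complete <- stage("estimate-complete", {
    rbindlist(lapply(names(val_prev), function(i) {
      cp <- complete_prevalence(regroup_to_empirical(val_prev[[i]]), model_idx)
      cp[, registry_id := i]
      cp
    }))
  })
  fwrite(complete, file.path(out_dir, "complete_prevalence.csv"))

  # --- validate (truncation APRD) ---
  validation <- stage("validate", {
    eligible <- names(val_prev)[vapply(val_prev, function(p)
      attr(p, "max_duration") >= 20L, TRUE)]
    if (length(eligible))
      truncation_validation(lapply(val_prev[eligible], regroup_to_empirical),
                            model_idx, config$truncations, target = 20L)
    else NULL
  })
  if (!is.null(validation)) fwrite(validation$aprd, file.path(out_dir, "validation_aprd.csv"))

  # --- compare methods (PRD) ---
  comparison <- stage("compare", {
    compare_methods(lapply(val_prev, regroup_to_empirical),
                    standard = model_idx,
                    alternatives = list(empirical = emp_idx))
  })
  fwrite(comparison$prd, file.path(out_dir, "comparison_prd.csv"))

  manifest$config <- list(
    registries = config$registries,
    estimation_registration_start = config$estimation_registration_start,
    index_date = format(config$index_date), truncations = config$truncations,
    sexes = config$sexes, pop_size = config$pop_size,
    scenarios = names(config$scenarios))
  manifest$outputs <- sort(list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(indexes = list(model = model_idx, empirical = emp_idx),
                 validation = validation, comparison = comparison,
                 complete = complete, manifest = manifest))
}
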