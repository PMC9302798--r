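#' Pipeline run configuration
#'
#' Assembles everything an end-to-end run needs: either a path to a
#' registry CSV or a [generator_config()] for synthetic input, the
#' classification and cohort-restriction settings, the simulation size, the
#' index ages and strata to report, and toggles for the cross-validating
#' analyses.
#'
#' @param registry_path optional path to a registry CSV; if `NULL` a
#'   synthetic registry is generated from `generator`.
#' @param generator a [generator_config()] (ignored when `registry_path`
#'   is given).
#' @param prediabetes_definition `"any"`, `"fpg_only"` or `"hba1c_only"`.
#' @param min_entry_age,min_followup cohort restrictions (years).
#' @param period_window optional calendar-year window for estimation.
#' @param sex_strata character vector of strata to estimate
#'   (subset of `"pooled"`, `"F"`, `"M"`).
#' @param n_sim simulated cohort size per stratum.
#' @param sim_start_age,sim_start_state simulation starting conditions.
#' @param index_ages index ages reported.
#' @param seed master seed; stage seeds derive from it.
#' @param run_mkm,run_sullivan,run_validation analysis toggles.
#' @return an object of class `run_config`.
#' @export
run_config <- function(registry_path = NULL,
                       generator = generator_config(n_persons = 20000L),
                       prediabetes_definition = "any",
                       min_entry_age = 0,
                       min_followup = 0,
                       period_window = NULL,
                       sex_strata = "pooled",
                       n_sim = 200000L,
                       sim_start_age = 0L,
                       sim_start_state = "NORMO",
                       index_ages = c(20L, 40L, 60L),
                       seed = 1L,
                       run_mkm = TRUE,
                       run_sullivan = TRUE,
                       run_validation = FALSE) {
  stopifnot(all(sex_strata %in% c("pooled", "F", "M")))
  if (!is.null(registry_path) && !file.exists(registry_path)) {
    stop("registry_path does not exist: ", registry_path)
  }
  structure(
    list(registry_path = registry_path, generator = generator,
         prediabetes_definition = match.arg(prediabetes_definition,
                                            c("any", "fpg_only", "hba1c_only")),
         min_entry_age = min_entry_age, min_followup = min_followup,
         period_window = period_window, sex_strata = sex_strata,
         n_sim = as.integer(n_sim), sim_start_age = as.integer(sim_start_age),
         sim_start_state = sim_start_state,
         index_ages = as.integer(index_ages), seed = as.integer(seed),
         run_mkm = isTRUE(run_mkm), run_sullivan = isTRUE(run_sullivan),
         run_validation = isTRUE(run_validation)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `generator`
#' section mirrors [generator_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  y$generator <- NULL
  gen <- if (is.null(gen_args)) generator_config(n_persons = 20000L) else {
    do.call(generator_config, gen_args)
  }
  do.call(run_config, c(y, list(generator = gen)))
}

#' Run the full lifetime-risk pipeline
#'
#' generate (or read) -> classify -> estimate -> simulate -> summarise,
#' with optional modified Kaplan-Meier, Sullivan and predicted-vs-observed
#' validation stages.  Identical configuration and seed give identical
#' outputs; every stage is timed and counted in the run log, and the
#' result bundle carries the configuration hash as provenance.
#'
#' @param config a [run_config()].
#' @return a list of class `run_bundle`: `config`, `config_hash`, `log`
#'   (stage, seconds, n), `histories`, `tables` (per stratum), `cohorts`
#'   (per stratum), `estimates` (tidy lifetime estimates), and optional
#'   `mkm`, `sullivan`, `validation`, `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  tick <- function(stage, n, t0) {
    log[[stage]] <<- data.frame(stage = stage, n = n,
                                seconds = round(as.numeric(Sys.time()) - t0, 3))
  }

  t0 <- as.numeric(Sys.time())
  registry <- if (!is.null(config$registry_path)) {
    read_registry(config$registry_path)
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    generate_registry(gen)
  }
  tick("generate", nrow(registry), t0)

  t0 <- as.numeric(Sys.time())
  study_end <- if (is.null(config$registry_path)) {
    config$generator$period_range[2]
  } else NULL
  histories <- resolve_histories(registry, config$prediabetes_definition,
                                 study_end = study_end)
  histories <- filter_cohort(histories, config$min_followup,
                             config$min_entry_age)
  if (nrow(histories) == 0L) stop("stage classify: no histories retained")
  tick("classify", nrow(histories), t0)

  t0 <- as.numeric(Sys.time())
  tables <- lapply(stats::setNames(config$sex_strata, config$sex_strata),
                   function(s) {
                     estimate_transitions(histories, sex = s,
                                          period_window = config$period_window)
                   })
  tick("estimate", length(tables), t0)

  t0 <- as.numeric(Sys.time())
  cohorts <- list()
  estimates <- list()
  for (s in config$sex_strata) {
    coh <- simulate_cohort(tables[[s]], n = config$n_sim,
                           seed = config$seed + 1000L,
                           start_age = config$sim_start_age,
                           start_state = config$sim_start_state)
    cohorts[[s]] <- coh
    for (ia in config$index_ages) {
      for (org in c("NORMO", "PRE")) {
        est <- lifetime_estimate(coh, ia, org)
        est$sex <- s
        estimates[[paste(s, ia, org)]] <- est
      }
    }
  }
  estimates <- data.table::rbindlist(estimates)
  data.table::setcolorder(estimates, "sex")
  tick("simulate", nrow(estimates), t0)

  bundle <- list(config = config, config_hash = rlang::hash(config),
                 histories = histories, tables = tables, cohorts = cohorts,
                 estimates = estimates)

  if (config$run_mkm) {
    t0 <- as.numeric(Sys.time())
    mkm <- list()
    for (ia in config$index_ages) {
      for (org in c("NORMO", "PRE")) {
        m <- modified_km_lifetime_risk(histories, org, ia)
        mkm[[paste(ia, org)]] <- data.frame(
          index_age = ia, origin_state = org, lifetime_risk = m$lifetime_risk,
          lo = m$lo, hi = m$hi, n_at_entry = m$n_at_entry,
          unstable = m$unstable)
      }
    }
    bundle$mkm <- data.table::rbindlist(mkm)
    tick("mkm", nrow(bundle$mkm), t0)
  }
  if (config$run_sullivan) {
    t0 <- as.numeric(Sys.time())
    bundle$sullivan <- lapply(cohorts, sullivan_from_cohort)
    tick("sullivan", length(bundle$sullivan), t0)
  }
  if (config$run_validation) {
    t0 <- as.numeric(Sys.time())
    bundle$validation <- validate_against_observed(
      cohorts[[config$sex_strata[1]]], histories)
    tick("validate", nrow(bundle$validation), t0)
  }
  bundle$log <- data.table::rbindlist(log)
  class(bundle) <- "run_bundle"
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("Lifetime-risk pipeline run", substr(x$config_hash, 1, 8), "\n")
  print(x$log)
  cat("\nLifetime estimates:\n")
  print(x$estimates)
  invisible(x)
}

#' Write a result bundle to a directory of CSVs plus a manifest
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "run_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(bundle$estimates, file.path(dir, "lifetime_estimates.csv"))
  write_histories(bundle$histories, file.path(dir, "histories.csv"))
  for (s in names(bundle$tables)) {
    write_transitions(bundle$tables[[s]],
                      file.path(dir, sprintf("transitions_%s.csv", s)))
  }
  if (!is.null(bundle$mkm)) {
    data.table::fwrite(bundle$mkm, file.path(dir, "mkm_lifetime_risk.csv"))
  }
  if (!is.null(bundle$sullivan)) {
    for (s in names(bundle$sullivan)) {
      data.table::fwrite(bundle$sullivan[[s]],
                         file.path(dir, sprintf("sullivan_%s.csv", s)))
    }
  }
  manifest <- list(config_hash = bundle$config_hash,
                   seed = bundle$config$seed,
                   created = format(Sys.time(), tz = "UTC"),
                   stages = bundle$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare lifetime-risk estimates between two populations
#'
#' Differences (population A minus population B) in lifetime risk per
#' (origin state, index age), with normal-approximation confidence bounds
#' from the per-population Monte Carlo intervals.  With
#' `substitute = TRUE`, population A's risks are first recomputed under
#' population B's mortality via [substitute_mortality()] (same simulation
#' size and derived seed), quantifying how much of the between-population
#' difference is attributable to differential mortality.
#'
#' @param bundle_a,bundle_b [run_pipeline()] results sharing index ages;
#'   the first sex stratum of each is compared.
#' @param substitute recompute A under B's mortality first.
#' @return a `data.frame` with `index_age`, `origin_state`, `risk_a`,
#'   `risk_b`, `difference`, `lo`, `hi`.
#' @export
compare_populations <- function(bundle_a, bundle_b, substitute = FALSE) {
  stopifnot(inherits(bundle_a, "run_bundle"), inherits(bundle_b, "run_bundle"))
  sa <- bundle_a$config$sex_strata[1]
  sb <- bundle_b$config$sex_strata[1]
  ea <- as.data.frame(bundle_a$estimates[bundle_a$estimates$sex == sa])
  eb <- as.data.frame(bundle_b$estimates[bundle_b$estimates$sex == sb])
  key <- c("index_age", "origin_state")
  miss <- setdiff(do.call(paste, eb[key]), do.call(paste, ea[key]))
  if (length(miss)) stop("mismatched strata: ", paste(miss, collapse = "; "))
  if (substitute) {
    tab_sub <- substitute_mortality(bundle_a$tables[[sa]],
                                    bundle_b$tables[[sb]])
    coh <- simulate_cohort(tab_sub, n = bundle_a$config$n_sim,
                           seed = bundle_a$config$seed + 2000L,
                           start_age = bundle_a$config$sim_start_age,
                           start_state = bundle_a$config$sim_start_state)
    ea <- do.call(rbind, lapply(seq_len(nrow(eb)), function(i) {
      cbind(remaining_lifetime_risk(coh, eb$index_age[i],
                                    eb$origin_state[i]))
    }))
  }
  m <- merge(ea[c(key, "lifetime_risk", "ci_lo", "ci_hi")],
             eb[c(key, "lifetime_risk", "ci_lo", "ci_hi")],
             by = key, suffixes = c("_a", "_b"))
  se <- function(lo, hi) (hi - lo) / (2 * 1.96)
  d_se <- sqrt(se(m$ci_lo_a, m$ci_hi_a)^2 + se(m$ci_lo_b, m$ci_hi_b)^2)
  data.frame(index_age = m$index_age, origin_state = m$origin_state,
             risk_a = m$lifetime_risk_a, risk_b = m$lifetime_risk_b,
             difference = m$lifetime_risk_a - m$lifetime_risk_b,
             lo = m$lifetime_risk_a - m$lifetime_risk_b - 1.96 * d_se,
             hi = m$lifetime_risk_a - m$lifetime_risk_b + 1.96 * d_se)
}
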