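#' Configuration of the synthetic surveillance registry generator
#'
#' Bundles the ground-truth dynamics and the observation process emulating
#' an electronic-medical-record glycemic surveillance database: entry at
#' arbitrary ages, irregular opportunistic testing with a large
#' single-measurement fraction, a mixture of measurement types dominated by
#' FPG and HbA1c with a small 2-hour OGTT share, inpatient and gestational
#' records (which downstream exclusion rules remove), right censoring, and
#' registered deaths.
#'
#' @param n_persons number of latent persons to generate (those who die or
#'   are censored before their first test never appear in the output, as in
#'   a real registry).
#' @param seed integer seed; output is byte-identical given the seed.
#' @param max_age maximum modelled age (capped at 110).
#' @param sex_ratio fraction of persons who are female.
#' @param entry_age_distribution list with `name` (`"uniform"` or
#'   `"constant"`) and its parameters (`min`/`max`, or `value`).
#' @param truth_transitions ground-truth dynamics: a single
#'   [transition_table()] applied to both sexes, or a list with elements `M`
#'   and `F`.  Default [default_truth_transitions()] per sex.
#' @param tests_per_year mean number of glycemic tests per observed year for
#'   people with more than one test.
#' @param single_test_fraction probability that a person has exactly one
#'   glycemic measurement (default 0.212).
#' @param measurement_mix named proportions of measurement kinds among
#'   FPG, HbA1c, OGTT2h, RPG; must sum to 1.
#' @param inpatient_fraction probability an FPG record is flagged inpatient.
#' @param gestational_fraction probability a measurement of a woman aged
#'   15-45 carries a gestational week (drawn uniformly in 4-42).
#' @param censor_rate per-year probability of right censoring (loss to
#'   follow-up, e.g. emigration; deaths after it go unregistered),
#'   exponential waiting time.  Default 0.005/year, the order of magnitude
#'   of net population movement in the surveilled region.
#' @param period_range calendar years covered by the registry; entry years
#'   are uniform over the range and observation stops at its end.
#' @param testing_schedule `"opportunistic"` (default: irregular tests with
#'   the configured per-year mean and single-test fraction) or `"annual"`
#'   (one test every year from entry to exit; removes interval censoring of
#'   onsets so estimator tests are isolated from observation-process
#'   effects).
#' @param testing_multiplier named multipliers of `tests_per_year` by latent
#'   state (`NORMO`, `PRE`, `DM`); default all 1 (testing intensity
#'   independent of the latent state).
#' @param dx_flag_rate,noninsulin_drug_rate,insulin_rate probabilities that
#'   a person with latent diabetes ever receives a diagnosis-code record, a
#'   non-insulin glucose-lowering-drug record, or a long (>= 28 days)
#'   insulin episode, each placed after latent onset.
#' @param short_insulin_rate probability that any person receives a short
#'   (< 28 days) insulin episode, which must not trigger a diabetes call.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_persons,
                             seed = 1L,
                             max_age = 110L,
                             sex_ratio = 0.5,
                             entry_age_distribution = list(name = "uniform",
                                                           min = 0, max = 90),
                             truth_transitions = NULL,
                             tests_per_year = 1.5,
                             single_test_fraction = 0.212,
                             measurement_mix = c(FPG = 0.60, HbA1c = 0.35,
                                                 OGTT2h = 0.014, RPG = 0.036),
                             inpatient_fraction = 0.05,
                             gestational_fraction = 0.02,
                             censor_rate = 0.005,
                             period_range = c(2001L, 2019L),
                             testing_schedule = c("opportunistic", "annual"),
                             testing_multiplier = c(NORMO = 1, PRE = 1, DM = 1),
                             dx_flag_rate = 0.2,
                             noninsulin_drug_rate = 0.3,
                             insulin_rate = 0.1,
                             short_insulin_rate = 0.005) {
  if (n_persons < 1) stop("n_persons must be at least 1")
  if (max_age > 110) stop("max_age must not exceed 110")
  if (is.null(truth_transitions)) {
    truth_transitions <- list(M = default_truth_transitions("M", 0:max_age),
                              F = default_truth_transitions("F", 0:max_age))
  }
  if (inherits(truth_transitions, "transition_table")) {
    truth_transitions <- list(M = truth_transitions, F = truth_transitions)
  }
  lapply(truth_transitions, validate_transition_table, tol = 1e-12)
  fracs <- c(sex_ratio = sex_ratio, single_test_fraction = single_test_fraction,
             inpatient_fraction = inpatient_fraction,
             gestational_fraction = gestational_fraction,
             censor_rate = censor_rate,
             dx_flag_rate = dx_flag_rate,
             noninsulin_drug_rate = noninsulin_drug_rate,
             insulin_rate = insulin_rate,
             short_insulin_rate = short_insulin_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop("probabilities/fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (!entry_age_distribution$name %in% c("uniform", "constant")) {
    stop("unknown entry age distribution: ", entry_age_distribution$name)
  }
  if (abs(sum(measurement_mix) - 1) > 1e-8) {
    stop("measurement_mix must sum to 1")
  }
  if (!all(names(measurement_mix) %in% .MEASUREMENT_KINDS)) {
    stop("measurement_mix names must be glycemic measurement kinds")
  }
  structure(
    list(n_persons = as.integer(n_persons), seed = as.integer(seed),
         max_age = as.integer(max_age), sex_ratio = sex_ratio,
         entry_age_distribution = entry_age_distribution,
         truth_transitions = truth_transitions,
         tests_per_year = tests_per_year,
         single_test_fraction = single_test_fraction,
         measurement_mix = measurement_mix,
         inpatient_fraction = inpatient_fraction,
         gestational_fraction = gestational_fraction,
         censor_rate = censor_rate,
         period_range = as.integer(period_range),
         testing_schedule = match.arg(testing_schedule),
         testing_multiplier = testing_multiplier,
         dx_flag_rate = dx_flag_rate,
         noninsulin_drug_rate = noninsulin_drug_rate,
         insulin_rate = insulin_rate,
         short_insulin_rate = short_insulin_rate),
    class = "generator_config"
  )
}

#' Ground-truth transition table of a generator configuration
#'
#' @param config a [generator_config()].
#' @param sex `"M"` or `"F"`.
#' @return the exact [transition_table()] that generated the latent
#'   trajectories, for parameter-recovery tests.
#' @export
export_truth <- function(config, sex = c("F", "M")) {
  stopifnot(inherits(config, "generator_config"))
  sex <- match.arg(sex)
  config$truth_transitions[[sex]]
}

# value bands the generator draws from per (kind, latent state); readings are
# uniform within the ADA band of the latent state, so classification recovers
# the latent state exactly
.value_band <- function(kind, state) {
  lo_all <- list(FPG = c(3.9, 5.6, 7.0), HbA1c = c(25, 39, 48),
                 OGTT2h = c(4.0, 7.8, 11.1))
  hi_all <- list(FPG = c(5.6, 7.0, 15.0), HbA1c = c(39, 48, 110),
                 OGTT2h = c(7.8, 11.1, 25.0))
  list(lo = lo_all[[kind]][state], hi = hi_all[[kind]][state])
}

#' Generate a synthetic glycemic surveillance registry
#'
#' First simulates each person's latent annual trajectory through the
#' four-state chain from the ground-truth transition table, then overlays an
#' opportunistic observation process.  Measurement values are drawn
#' uniformly within the ADA band of the latent state at the test age, so a
#' correct classifier recovers the latent state without misclassification
#' noise; deaths occurring before censoring are registered.
#'
#' @param config a [generator_config()].
#' @return a `data.table` of records with columns `person_id`, `sex`,
#'   `birth_year`, `event_age`, `record_kind`, `value`, `inpatient`,
#'   `gestational_week`, `insulin_days`, sorted by person and age.  The
#'   latent trajectories are attached as attribute `"latent"` (a
#'   `data.table` keyed by `person_id` with latent onset/death/censor ages)
#'   for diagnostic and recovery testing.
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_persons
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")

  # latent annual trajectories per sex, from birth
  lat <- data.table::data.table(pre = NA_integer_, dm = NA_integer_,
                                dth = NA_integer_)[rep(1L, n)]
  for (s in c("F", "M")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    coh <- simulate_cohort(config$truth_transitions[[s]], n = length(idx),
                           seed = NULL, start_age = 0L)
    lat$pre[idx] <- coh$pre_onset
    lat$dm[idx] <- coh$dm_onset
    lat$dth[idx] <- coh$death_age
  }
  # continuous death time inside the transition year
  death_cont <- ifelse(is.na(lat$dth), Inf,
                       lat$dth - 1L + stats::runif(n))

  ead <- config$entry_age_distribution
  entry <- switch(ead$name,
    uniform = stats::runif(n, ead$min, ead$max),
    constant = rep(ead$value, n)
  )
  entry_year <- sample(seq(config$period_range[1], config$period_range[2]),
                       n, replace = TRUE)
  birth_year <- entry_year - floor(entry)
  admin_end_age <- config$period_range[2] + 1L - birth_year
  censor_age <- entry + stats::rexp(n, rate = max(config$censor_rate, 1e-12))
  exit_obs <- pmin(death_cont, censor_age, admin_end_age, config$max_age + 1)

  observed <- entry < exit_obs
  state_at <- function(age_int, i) {
    # latent state code at integer age for person index i
    s <- rep(1L, length(i))
    s[!is.na(lat$pre[i]) & age_int >= lat$pre[i]] <- 2L
    s[!is.na(lat$dm[i]) & age_int >= lat$dm[i]] <- 3L
    s
  }

  pid <- sprintf("p%07d", seq_len(n))
  recs <- list()

  # --- glycemic tests -------------------------------------------------------
  oi <- which(observed)
  if (config$testing_schedule == "annual") {
    # one test every year from entry until exit
    n_extra <- pmax(ceiling(exit_obs[oi] - entry[oi]) - 1L, 0L)
    test_person <- rep(oi, n_extra + 1L)
    offs <- sequence(n_extra + 1L) - 1L
    t_age <- entry[test_person] + offs
    keep <- t_age < exit_obs[test_person]
    test_person <- test_person[keep]
    t_age <- t_age[keep]
  } else {
    singleton <- stats::runif(length(oi)) < config$single_test_fraction
    followup <- exit_obs[oi] - entry[oi]
    mult <- config$testing_multiplier
    state_entry <- state_at(floor(entry[oi]), oi)
    lam <- config$tests_per_year * unname(mult[c("NORMO", "PRE", "DM")][state_entry])
    n_extra <- ifelse(singleton, 0L, 1L + stats::rpois(length(oi), lam * followup))
    test_person <- rep(oi, n_extra + 1L)
    first <- sequence(n_extra + 1L) == 1L
    t_age <- numeric(length(test_person))
    t_age[first] <- entry[oi]
    extra_per <- rep(oi, n_extra)
    t_age[!first] <- stats::runif(length(extra_per), entry[extra_per],
                                  exit_obs[extra_per])
  }
  kinds <- sample(names(config$measurement_mix), length(test_person),
                  replace = TRUE, prob = config$measurement_mix)
  st <- state_at(floor(t_age), test_person)
  value <- numeric(length(test_person))
  rpg <- kinds == "RPG"
  value[rpg] <- stats::runif(sum(rpg), 4, 12)
  for (k in c("FPG", "HbA1c", "OGTT2h")) {
    for (s0 in 1:3) {
      sel <- kinds == k & st == s0
      if (!any(sel)) next
      b <- .value_band(k, s0)
      value[sel] <- stats::runif(sum(sel), b$lo, b$hi)
    }
  }
  inpat <- kinds == "FPG" & stats::runif(length(test_person)) < config$inpatient_fraction
  fertile <- sex[test_person] == "F" & t_age >= 15 & t_age <= 45
  gest <- fertile & stats::runif(length(test_person)) < config$gestational_fraction
  gest_week <- rep(NA_integer_, length(test_person))
  gest_week[gest] <- sample(4:42, sum(gest), replace = TRUE)
  recs$tests <- data.table::data.table(
    person = test_person, event_age = t_age, record_kind = kinds,
    value = value, inpatient = inpat, gestational_week = gest_week,
    insulin_days = NA_integer_
  )

  # --- clinical flags for latent diabetes ----------------------------------
  dm_flag <- function(rate, kind, days_fun = NULL) {
    cand <- which(observed & !is.na(lat$dm))
    cand <- cand[stats::runif(length(cand)) < rate]
    if (!length(cand)) return(NULL)
    age <- pmax(lat$dm[cand], entry[cand]) + stats::rexp(length(cand), 0.5)
    keep <- age < exit_obs[cand]
    cand <- cand[keep]; age <- age[keep]
    if (!length(cand)) return(NULL)
    data.table::data.table(
      person = cand, event_age = age, record_kind = kind, value = NA_real_,
      inpatient = FALSE, gestational_week = NA_integer_,
      insulin_days = if (is.null(days_fun)) NA_integer_ else days_fun(length(cand))
    )
  }
  recs$dx <- dm_flag(config$dx_flag_rate, "dx_code")
  recs$drug <- dm_flag(config$noninsulin_drug_rate, "noninsulin_drug")
  recs$insulin <- dm_flag(config$insulin_rate, "insulin_episode",
                          function(k) 28L + stats::rpois(k, 60))
  # short insulin episodes (< 28 days) that must never trigger diabetes
  si <- which(observed & stats::runif(n) < config$short_insulin_rate)
  if (length(si)) {
    age <- stats::runif(length(si), entry[si], exit_obs[si])
    recs$short_insulin <- data.table::data.table(
      person = si, event_age = age, record_kind = "insulin_episode",
      value = NA_real_, inpatient = FALSE, gestational_week = NA_integer_,
      insulin_days = sample(1:27, length(si), replace = TRUE)
    )
  }

  # --- registered deaths ----------------------------------------------------
  dd <- which(observed & death_cont < pmin(censor_age, admin_end_age,
                                           config$max_age + 1))
  if (length(dd)) {
    recs$death <- data.table::data.table(
      person = dd, event_age = death_cont[dd], record_kind = "death",
      value = NA_real_, inpatient = FALSE, gestational_week = NA_integer_,
      insulin_days = NA_integer_
    )
  }

  out <- data.table::rbindlist(recs, use.names = TRUE)
  out[, `:=`(person_id = pid[person], sex = sex[person],
             birth_year = birth_year[person])]
  out[, person := NULL]
  data.table::setcolorder(out, c("person_id", "sex", "birth_year",
                                 "event_age", "record_kind", "value",
                                 "inpatient", "gestational_week",
                                 "insulin_days"))
  data.table::setorder(out, person_id, event_age)
  latent <- data.table::data.table(
    person_id = pid, sex = sex, birth_year = birth_year,
    entry_age = entry, latent_pre = lat$pre, latent_dm = lat$dm,
    latent_death = ifelse(is.infinite(death_cont), NA_real_, death_cont),
    censor_age = pmin(censor_age, admin_end_age, config$max_age + 1),
    observed = observed
  )
  data.table::setattr(out, "latent", latent)
  out[]
}

#' Write a registry to CSV (one row per record; missing fields empty)
#'
#' @param registry a [generate_registry()] result (or compatible table).
#' @param path output file path.
#' @export
write_registry <- function(registry, path) {
  data.table::fwrite(registry, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  out <- data.table::fread(path, na.strings = c("", "NA"))
  out$inpatient <- as.logical(out$inpatient)
  out[]
}
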