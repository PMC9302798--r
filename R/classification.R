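#' Exclude stress- and pregnancy-related glycemic records
#'
#' Removes FPG records taken during hospital admissions
#' (`inpatient = TRUE`) and any glycemic measurement taken within
#' gestational weeks 24 to 40, which would otherwise misclassify
#' stress-induced or gestational hyperglycemia.  All other records pass
#' through unchanged, in their original order; absent flags are treated as
#' not set.  The operation is idempotent.
#'
#' @param records a registry `data.frame`/`data.table` in the
#'   [generate_registry()] layout.
#' @return the filtered records.
#' @export
apply_exclusions <- function(records) {
  records <- data.table::as.data.table(records)
  inpat <- if ("inpatient" %in% names(records)) {
    !is.na(records$inpatient) & records$inpatient
  } else rep(FALSE, nrow(records))
  gest <- if ("gestational_week" %in% names(records)) {
    !is.na(records$gestational_week) &
      records$gestational_week >= 24 & records$gestational_week <= 40
  } else rep(FALSE, nrow(records))
  is_meas <- records$record_kind %in% .MEASUREMENT_KINDS
  drop <- (inpat & records$record_kind == "FPG") | (gest & is_meas)
  records[!drop]
}

# per-record diabetes evidence age (NA if the record is not diabetes
# evidence) and prediabetes evidence age under a given definition
.dm_evidence <- function(records) {
  kind <- records$record_kind
  age <- records$event_age
  ev <- rep(NA_real_, nrow(records))
  flag <- kind %in% c("dx_code", "noninsulin_drug")
  ev[flag] <- age[flag]
  ins <- kind == "insulin_episode" & !is.na(records$insulin_days) &
    records$insulin_days >= 28
  ev[ins] <- age[ins]
  meas <- kind %in% names(.GLYCEMIC_BANDS)
  if (any(meas)) {
    cls <- classify_measurement(kind[meas], records$value[meas])
    ev[meas][cls == "DM"] <- age[meas][cls == "DM"]
  }
  ev
}

.pre_evidence <- function(records, prediabetes_definition) {
  kinds <- switch(prediabetes_definition,
    any = names(.GLYCEMIC_BANDS),
    fpg_only = "FPG",
    hba1c_only = "HbA1c",
    stop("unknown prediabetes definition: ", prediabetes_definition)
  )
  ev <- rep(NA_real_, nrow(records))
  meas <- records$record_kind %in% kinds
  if (any(meas)) {
    cls <- classify_measurement(records$record_kind[meas], records$value[meas])
    ev[meas][cls == "PRE"] <- records$event_age[meas][cls == "PRE"]
  }
  ev
}

#' Resolve per-person state histories from registry records
#'
#' Applies the diagnostic criteria to each person's records and produces
#' one row per person summarising the resolved trajectory through
#' normoglycemia, prediabetes, diabetes and death.
#'
#' Diabetes onset is the earliest age at which any criterion holds: a
#' diagnosis code, a non-insulin glucose-lowering drug, an insulin episode
#' of at least 28 continuous days, FPG >= 7.0 mmol/L, HbA1c >= 48 mmol/mol,
#' or 2-hour OGTT >= 11.1 mmol/L.  Prediabetes onset is the earliest
#' qualifying measurement under the chosen definition strictly before
#' diabetes onset (evidence tied at the same age resolves to diabetes by
#' severity).  States never revert; onsets are binned to integer ages by
#' `floor()` when annualised.  Entry is the first glycemic measurement;
#' persons without any glycemic measurement after exclusions are dropped.
#'
#' @param records registry records, already passed through
#'   [apply_exclusions()] (running them through again is harmless).
#' @param prediabetes_definition `"any"` (default), `"fpg_only"` or
#'   `"hba1c_only"`; only affects prediabetes onsets, never diabetes onsets.
#' @param study_end optional last calendar year of surveillance.  When
#'   given (and birth years are known), vital status is taken as registered
#'   until the administrative end of surveillance, so a person in the
#'   absorbing diabetes state with no death record is known alive until
#'   then; without it, knowledge stops at the last record.
#' @return a `data.table` with one row per person: `person_id`, `sex`,
#'   `birth_year`, `entry_age`, `pre_onset_age`, `dm_onset_age`,
#'   `death_age`, `censor_age` (last record age), `last_meas_age` (last
#'   glycemic measurement age), `vital_end_age` (end of vital-status
#'   coverage), `n_measurements`, `followup_years`.
#' @export
resolve_histories <- function(records, prediabetes_definition = "any",
                              study_end = NULL) {
  records <- apply_exclusions(records)
  if (nrow(records) == 0L) stop("no records to resolve")
  dt <- data.table::as.data.table(records)
  dt[, `:=`(dm_ev = .dm_evidence(dt),
            pre_ev = .pre_evidence(dt, prediabetes_definition),
            is_meas = record_kind %in% .MEASUREMENT_KINDS,
            is_death = record_kind == "death")]
  # cohort entry requires a qualifying measurement (FPG/HbA1c/OGTT);
  # random plasma glucose alone neither qualifies a person for inclusion
  # nor informs the glycemic state
  dt[, is_qual := record_kind %in% names(.GLYCEMIC_BANDS)]
  min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  h <- dt[, list(
    sex = sex[1L],
    birth_year = birth_year[1L],
    entry_age = min_na(event_age[is_qual]),
    dm_onset_age = min_na(dm_ev),
    pre_cand = min_na(pre_ev),
    death_age = min_na(event_age[is_death]),
    censor_age = max(event_age),
    last_meas_age = max_na(event_age[is_qual]),
    n_measurements = sum(is_qual),
    n_death_records = sum(is_death)
  ), by = person_id]
  if (any(h$n_death_records > 1L)) {
    stop("more than one death record for person(s): ",
         paste(utils::head(h$person_id[h$n_death_records > 1L]), collapse = ", "))
  }
  post_death <- dt[h[!is.na(death_age)], on = "person_id"][event_age > death_age]
  if (nrow(post_death) > 0L) {
    stop("records after death age for person(s): ",
         paste(unique(utils::head(post_death$person_id)), collapse = ", "))
  }
  h <- h[n_measurements > 0L]
  # ties at the same age between PRE and DM evidence resolve to DM
  h[, pre_onset_age := data.table::fifelse(
    !is.na(pre_cand) & (is.na(dm_onset_age) | pre_cand < dm_onset_age),
    pre_cand, NA_real_)]
  h[, `:=`(pre_cand = NULL, n_death_records = NULL)]
  h[, followup_years := censor_age - entry_age]
  if (!is.null(study_end)) {
    h[, vital_end_age := data.table::fifelse(
      is.na(birth_year), censor_age,
      pmax(pmin(study_end + 1 - birth_year, 111), censor_age))]
  } else {
    # without a known administrative end, a registered death is itself
    # evidence that vital status was covered through the death year
    h[, vital_end_age := data.table::fifelse(
      is.na(death_age), censor_age, floor(death_age) + 1)]
  }
  data.table::setcolorder(h, c("person_id", "sex", "birth_year", "entry_age",
                               "pre_onset_age", "dm_onset_age", "death_age",
                               "censor_age", "last_meas_age", "vital_end_age",
                               "n_measurements", "followup_years"))
  h[]
}

#' @rdname resolve_histories
#' @details `resolve_state_history()` resolves a single person and errors if
#'   records from more than one person (or none) are supplied.
#' @export
resolve_state_history <- function(records, prediabetes_definition = "any",
                                  study_end = NULL) {
  if (nrow(records) == 0L) stop("empty record set")
  if (length(unique(records$person_id)) > 1L) {
    stop("records from more than one person")
  }
  resolve_histories(records, prediabetes_definition, study_end)
}

#' Annualised state sequence of a resolved history
#'
#' The state at integer age `a` is the most severe state whose onset
#' (binned by `floor()`) is at or before `a`; states never revert and are
#' carried forward, so the sequence runs from `floor(entry_age)` to the end
#' of vital-status coverage (the floor of the death age when the person
#' died, followed by DEATH; otherwise the floor of `vital_end_age`).
#'
#' @param history a one-row resolved history (see [resolve_histories()]).
#' @return a `data.frame` with columns `age` and `state`.
#' @export
state_sequence <- function(history) {
  stopifnot(nrow(history) == 1L)
  w <- .obs_windows(history)
  ages <- seq.int(w$fe, w$K)
  st <- state_levels()[.state_code_at(ages, w$pref, w$dmf)]
  if (w$death_trans) {
    ages <- c(ages, w$K + 1L)
    st <- c(st, "DEATH")
  }
  data.frame(age = ages, state = st)
}

# integer state code at integer age(s) given floored onset ages (NA = never)
.state_code_at <- function(age, pref, dmf) {
  s <- rep(1L, length(age))
  s[!is.na(pref) & age >= pref] <- 2L
  s[!is.na(dmf) & age >= dmf] <- 3L
  s
}

# end of vital-status coverage (falls back to the last record age for
# histories resolved without a study end)
.vital_end <- function(h) {
  if ("vital_end_age" %in% names(h)) h$vital_end_age else h$censor_age
}

# Observation windows for discrete transition counting (vectorised over
# histories).  Returns floored entry fe, floored onsets pref/dmf, the
# knowledge horizon K (last integer age with a deducible state) and whether
# a death transition is attributable at age K.
#
# Under the operational state definitions every living state is carried
# forward (no reversion: once classified, a person keeps the state until
# evidence of the next one), so the state at any age between entry and the
# end of vital-status coverage is deducible, and every registered death is
# attributed to the carried state.  Vital coverage ends at the
# administrative end of surveillance when the histories were resolved with
# a `study_end` (deaths are registered independently of testing), and at
# the last record otherwise.  Person-time before entry is never counted.
.obs_windows <- function(h, max_age = 110L) {
  fe <- pmax(floor(h$entry_age), 0)
  pref <- floor(h$pre_onset_age)
  dmf <- floor(h$dm_onset_age)
  dthf <- floor(h$death_age)
  has_dth <- !is.na(dthf)
  K <- ifelse(has_dth, dthf, floor(.vital_end(h)))
  death_trans <- has_dth & K <= max_age & K >= fe
  K <- pmin(K, max_age)
  list(fe = fe, pref = pref, dmf = dmf, K = K, death_trans = death_trans)
}

#' Filter resolved histories by follow-up duration and entry age
#'
#' @param histories resolved histories (see [resolve_histories()]).
#' @param min_followup minimum follow-up in years (default 0).
#' @param min_entry_age minimum entry age in years (default 0).
#' @return the retained histories.
#' @export
filter_cohort <- function(histories, min_followup = 0, min_entry_age = 0) {
  if (min_followup < 0 || min_entry_age < 0) {
    stop("thresholds must be non-negative")
  }
  histories <- data.table::as.data.table(histories)
  histories[followup_years >= min_followup & entry_age >= min_entry_age]
}

#' Write / read resolved histories as CSV
#'
#' @param histories resolved histories.
#' @param path file path.
#' @export
write_histories <- function(histories, path) {
  data.table::fwrite(histories, path)
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  data.table::fread(path, na.strings = c("", "NA"))[]
}
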