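#' Estimate age-specific one-year transition probabilities
#'
#' Discrete-time occurrence/exposure estimator with age as the clock:
#' for each integer age `a` and origin state `s`,
#' `P[a, s, s'] = (observed s -> s' transitions between a and a+1) /
#' (persons in s at age a whose status at a+1 is known)`.
#'
#' A person contributes to an at-risk set at age `a` only when the
#' corresponding destination status at `a + 1` is known or deducible, and
#' the two destination families are observed by different processes, so
#' each uses its own exposure window:
#' \itemize{
#'   \item Progression among living states is observable only through
#'     qualifying measurements; its risk set at age `a` requires a
#'     qualifying measurement at or after age `a + 1`, and the conditional
#'     progression probability given survival is estimated there.  Onsets
#'     are dated at the first qualifying evidence (right-endpoint
#'     convention) and states never revert, so states between measurements
#'     are deducible.
#'   \item Death is registered independently of testing; its risk set at
#'     age `a` requires vital-status coverage through `a + 1`
#'     ([resolve_histories()]'s `study_end`-based coverage, or the last
#'     record without one), which counts deaths and survivors over the
#'     same fully covered one-year intervals.
#' }
#' The row at `(a, s)` is assembled as `P(s -> DEATH) = q`,
#' `P(s -> s') = (1 - q) p'` for living destinations `s' != s` with `p'`
#' the conditional progression estimate, and the diagonal as the
#' remainder.  Person-time before entry never contributes (no
#' immortal-time bias).
#'
#' Ages with no at-risk person in an origin state borrow the row of the
#' nearest populated age within the same stratum (recorded in the
#' `borrowed` slot), so the chain is defined on the whole age range.
#'
#' @param histories resolved histories (see [resolve_histories()]).
#' @param sex `"M"`, `"F"` or `"pooled"` (default: all persons).
#' @param period_window optional length-2 integer vector of calendar years;
#'   only transitions whose age-`a` year falls inside the window contribute
#'   (requires `birth_year`).
#' @param max_age upper age of the table (default 110).
#' @return a [transition_table()] with probabilities, transition counts and
#'   at-risk counts (`n_at_risk` is the progression risk set for living
#'   destinations and the vital risk set for the diabetes row;
#'   `n_at_risk_death` carries the vital risk set of every living state).
#' @export
estimate_transitions <- function(histories, sex = "pooled",
                                 period_window = NULL, max_age = 110L) {
  sex <- match.arg(sex, c("M", "F", "pooled"))
  h <- data.table::as.data.table(histories)
  if (sex != "pooled") {
    keep_rows <- which(h[["sex"]] == sex)  # plain index: avoids i-scope capture
    h <- h[keep_rows]
  }
  if (nrow(h) == 0L) stop("no histories contribute person-time in stratum: ", sex)

  rows <- .person_age_rows(h, max_age)
  if (!is.null(period_window)) {
    for (k in c("glyc", "vital")) {
      by_ <- h$birth_year[rows[[k]]$person]
      rows[[k]] <- rows[[k]][!is.na(by_) & by_ + rows[[k]]$age >= period_window[1] &
                               by_ + rows[[k]]$age <= period_window[2]]
    }
  }
  if (nrow(rows$glyc) + nrow(rows$vital) == 0L) {
    stop("no transitions observed in stratum: ", sex)
  }

  ages <- 0:max_age
  nA <- length(ages)
  # progression (conditional on survival): counts by (age, from, to in 1:3)
  n_trans <- array(0L, dim = c(nA, 4, 4))
  cg <- rows$glyc[, .N, by = list(age, from, to)]
  n_trans[cbind(cg$age + 1L, cg$from, cg$to)] <- cg$N
  n_glyc <- apply(n_trans, c(1, 2), sum)
  # deaths over fully covered vital intervals
  cv <- rows$vital[, list(n = .N, d = sum(dead)), by = list(age, from)]
  n_vital <- matrix(0L, nA, 4)
  d_death <- matrix(0L, nA, 4)
  n_vital[cbind(cv$age + 1L, cv$from)] <- cv$n
  d_death[cbind(cv$age + 1L, cv$from)] <- cv$d
  for (s in 1:4) n_trans[cbind(seq_len(nA), s, 4L)] <- as.integer(d_death[, s])

  assemble <- function(ai, s) {
    q <- if (n_vital[ai, s] > 0) d_death[ai, s] / n_vital[ai, s] else 0
    p <- numeric(4)
    p[4] <- q
    if (s < 3 && n_glyc[ai, s] > 0) {
      cond <- n_trans[ai, s, 1:3] / n_glyc[ai, s]
      p[1:3] <- (1 - q) * cond
    } else {
      p[s] <- 1 - q
    }
    p
  }
  populated <- function(ai, s) {
    if (s == 3L) n_vital[ai, s] > 0 else n_glyc[ai, s] > 0 || n_vital[ai, s] > 0
  }
  P <- array(0, dim = c(nA, 4, 4))
  borrowed <- matrix(FALSE, nA, 4)
  n_at_risk <- matrix(0L, nA, 4)
  for (s in 1:3) {
    pop <- which(vapply(seq_len(nA), populated, logical(1), s = s))
    for (ai in seq_len(nA)) {
      if (populated(ai, s)) {
        P[ai, s, ] <- assemble(ai, s)
      } else if (length(pop)) {
        src <- pop[which.min(abs(pop - ai))]
        P[ai, s, ] <- assemble(src, s)
        borrowed[ai, s] <- TRUE
      } else {
        P[ai, s, s] <- 1  # state never observed: inert fallback
        borrowed[ai, s] <- TRUE
      }
    }
    n_at_risk[, s] <- if (s == 3L) n_vital[, s] else n_glyc[, s]
  }
  P[, 4, 4] <- 1
  tab <- transition_table(P, n_trans = n_trans, n_at_risk = n_at_risk,
                          sex = sex, ages = ages, borrowed = borrowed)
  tab$n_at_risk_death <- n_vital
  tab
}

# Person-age exposure rows under the two observability processes.
#
# `glyc`: one row per (person, age a) with a qualifying measurement at or
# after a+1 and the person alive in a living state at a; `from`/`to` are
# the carried states at a and a+1 (living destinations only).  Onsets are
# floor-dated: a state detected during a year is the state at that integer
# age, matching the annual latent convention.
#
# `vital`: one row per (person, age a) with vital coverage through a+1 and
# the person alive at a; `dead` marks a registered death during [a, a+1).
# Here the state and entry are ceiling-dated (state at the start of the
# interval): detection and registry entry happen mid-year conditional on
# being alive at that moment, so attributing the switch/entry year to the
# new state would credit it with survivor-only person-time and push its
# deaths onto the origin state.  Assigning the whole switch year to the
# origin state and dropping the partial entry year keeps every one-year
# death interval fully exposed.
.person_age_rows <- function(h, max_age = 110L) {
  fe <- pmax(floor(h$entry_age), 0)
  pref <- floor(h$pre_onset_age)
  dmf <- floor(h$dm_onset_age)
  dthf <- floor(h$death_age)
  G <- pmin(floor(h$last_meas_age), max_age)
  ve <- floor(.vital_end(h))

  # progression rows: a in fe .. G-1 (alive at a+1 is implied: qualifying
  # measurements only happen in life)
  len <- pmax(G - fe, 0)
  idx <- rep(seq_len(nrow(h)), len)
  a <- sequence(len) - 1L + fe[idx]
  glyc <- data.table::data.table(
    person = idx, age = a,
    from = .state_code_at(a, pref[idx], dmf[idx]),
    to = .state_code_at(a + 1L, pref[idx], dmf[idx])
  )

  # vital rows: a in ceiling(entry) .. min(ve - 1, dthf, max_age)
  fe_v <- pmax(ceiling(h$entry_age), 0)
  pref_v <- ceiling(h$pre_onset_age)
  dmf_v <- ceiling(h$dm_onset_age)
  last_v <- pmin(ve - 1L, ifelse(is.na(dthf), max_age, dthf), max_age)
  lenv <- pmax(last_v - fe_v + 1L, 0)
  idxv <- rep(seq_len(nrow(h)), lenv)
  av <- sequence(lenv) - 1L + fe_v[idxv]
  vital <- data.table::data.table(
    person = idxv, age = av,
    from = .state_code_at(av, pref_v[idxv], dmf_v[idxv]),
    dead = !is.na(dthf[idxv]) & av == dthf[idxv]
  )
  list(glyc = glyc, vital = vital)
}

#' Incidence rate per 1,000 person-years
#'
#' @param events number of incident events.
#' @param person_years person-years at risk.
#' @return the rate per 1,000 person-years.
#' @examples
#' incidence_rate(250175, 5767846)   # 43.4 per 1,000 PY
#' incidence_rate(122705, 11412840)  # 10.8 per 1,000 PY
#' @export
incidence_rate <- function(events, person_years) {
  if (any(person_years <= 0)) stop("undefined rate: zero person-years")
  events / person_years * 1000
}

#' Crude incidence of progression between glycemic states
#'
#' Events per 1,000 person-years at risk, with person-time accrued from the
#' onset of the origin state (entry for normoglycemia) until the event,
#' death, or censoring, whichever comes first.  For origin normoglycemia
#' the person must be normoglycemic at entry, and follow-up towards
#' diabetes continues through an intermediate prediabetes phase.
#'
#' @param histories resolved histories.
#' @param origin_state `"NORMO"` or `"PRE"`.
#' @param event_state `"PRE"` or `"DM"` (must be more severe than origin).
#' @return a list with `rate` (per 1,000 PY), `events`, `person_years`,
#'   `n_at_risk` (persons contributing).
#' @export
crude_incidence <- function(histories, origin_state = "PRE",
                            event_state = "DM") {
  h <- data.table::as.data.table(histories)
  oi <- state_index(origin_state); ei <- state_index(event_state)
  if (oi >= ei || ei == .STATE_X) {
    stop("origin must precede event in severity order")
  }
  if (origin_state == "PRE") {
    sel <- !is.na(h$pre_onset_age)
    baseline <- pmax(h$pre_onset_age, h$entry_age)
  } else {
    # normoglycemic at entry
    sel <- (is.na(h$pre_onset_age) | h$pre_onset_age > h$entry_age) &
      (is.na(h$dm_onset_age) | h$dm_onset_age > h$entry_age)
    baseline <- h$entry_age
  }
  ev_age <- if (event_state == "DM") h$dm_onset_age else h$pre_onset_age
  end <- pmin(ifelse(is.na(ev_age), Inf, ev_age),
              ifelse(is.na(h$death_age), Inf, h$death_age),
              h$censor_age)
  sel <- sel & end > baseline
  events <- sum(sel & !is.na(ev_age) &
                  ev_age <= ifelse(is.na(h$death_age), Inf, h$death_age) &
                  ev_age <= h$censor_age)
  py <- sum((end - baseline)[sel])
  if (py <= 0) stop("undefined rate: zero person-years")
  list(rate = incidence_rate(events, py), events = events,
       person_years = py, n_at_risk = sum(sel))
}
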