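#' Simulate individual trajectories through the four-state Markov chain
#'
#' Draws `n` independent annual trajectories from a one-year transition
#' table, starting in `start_state` at `start_age` and advancing with a
#' cycle length of one year until death or the terminal age (the last age of
#' the table, 110 by default).  Individuals still alive at the terminal age
#' are truncated there; the truncation is recorded by a missing death age.
#'
#' Trajectories are stored compressed as first-occupancy ages:
#' `pre_onset` / `dm_onset` / `death_age` are the integer ages at which the
#' person first occupies PRE / DM / DEATH (`NA` if never).  A person whose
#' death age is `a` was alive at ages up to `a - 1`.
#'
#' @param table a [transition_table()] with stochastic rows at every age
#'   from `start_age` to the end of its age range.
#' @param n number of individuals to simulate.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param start_age integer age at which everyone starts (default 0).
#' @param start_state state label everyone starts in (default `"NORMO"`).
#' @return an object of class `simulated_cohort`: a `data.table` with columns
#'   `pre_onset`, `dm_onset`, `death_age` and attributes `start_age`,
#'   `terminal_age`, `sex`, `seed`.
#' @examples
#' tab <- default_truth_transitions("F")
#' coh <- simulate_cohort(tab, n = 1000, seed = 1)
#' mean(!is.na(coh$dm_onset))  # lifetime probability of diabetes from birth
#' @export
simulate_cohort <- function(table, n, seed = NULL, start_age = 0L,
                            start_state = "NORMO") {
  stopifnot(inherits(table, "transition_table"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ages <- table$ages
  terminal <- max(ages)
  if (start_age < min(ages) || start_age > terminal) {
    stop("start_age outside the table's age range")
  }
  P <- table$P
  bad <- which(abs(apply(P, c(1, 2), sum) - 1) > 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-stochastic row at age %s, state %s",
                 ages[bad[1, 1]], state_levels()[bad[1, 2]]))
  }
  s0 <- state_index(start_state)
  if (s0 == .STATE_X) stop("cannot start a trajectory in DEATH")
  state <- rep.int(s0, n)
  pre <- dm <- dth <- rep(NA_integer_, n)
  if (s0 >= .STATE_P) pre <- rep.int(as.integer(start_age), n)
  if (s0 >= .STATE_D) dm <- rep.int(as.integer(start_age), n)
  for (a in start_age:(terminal - 1L)) {
    ai <- match(a, ages)
    u <- stats::runif(n)
    nxt <- state
    for (s in 1:3) {
      idx <- which(state == s)
      if (!length(idx)) next
      cp <- cumsum(P[ai, s, ])
      nxt[idx] <- 1L + findInterval(u[idx], cp[1:3])
    }
    newly_pre <- is.na(pre) & nxt == .STATE_P
    newly_dm <- is.na(dm) & nxt == .STATE_D
    newly_dead <- is.na(dth) & nxt == .STATE_X
    pre[newly_pre] <- a + 1L
    dm[newly_dm] <- a + 1L
    dth[newly_dead] <- a + 1L
    state <- nxt
  }
  out <- data.table::data.table(pre_onset = pre, dm_onset = dm, death_age = dth)
  data.table::setattr(out, "start_age", as.integer(start_age))
  data.table::setattr(out, "terminal_age", as.integer(terminal))
  data.table::setattr(out, "sex", table$sex)
  data.table::setattr(out, "seed", seed)
  data.table::setattr(out, "class", c("simulated_cohort", class(out)))
  out
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %s individuals (%s), ages %d-%d\n",
              format(nrow(x), big.mark = ","), attr(x, "sex"),
              attr(x, "start_age"), attr(x, "terminal_age")))
  cat(sprintf("  developed prediabetes: %s; diabetes: %s; died in horizon: %s\n",
              format(sum(!is.na(x$pre_onset)), big.mark = ","),
              format(sum(!is.na(x$dm_onset)), big.mark = ","),
              format(sum(!is.na(x$death_age)), big.mark = ",")))
  invisible(x)
}

# age at which the person stops contributing alive person-time:
# recorded death age, or the terminal age for those truncated alive
.end_age <- function(cohort) {
  t_age <- attr(cohort, "terminal_age")
  ifelse(is.na(cohort$death_age), t_age, cohort$death_age)
}

# logical index of cohort members occupying `origin` at `index_age`
# (alive; "ANY" = any living state)
.occupies_at <- function(cohort, index_age, origin) {
  alive <- is.na(cohort$death_age) | cohort$death_age > index_age
  pre <- cohort$pre_onset
  dm <- cohort$dm_onset
  in_state <- switch(origin,
    NORMO = (is.na(pre) | pre > index_age) & (is.na(dm) | dm > index_age),
    PRE = !is.na(pre) & pre <= index_age & (is.na(dm) | dm > index_age),
    DM = !is.na(dm) & dm <= index_age,
    ANY = rep(TRUE, nrow(cohort)),
    stop("unknown origin state: ", origin)
  )
  alive & in_state
}

#' Remaining lifetime risk of diabetes from a simulated cohort
#'
#' The proportion of people who eventually develop diabetes among those
#' occupying `origin_state` (alive and diabetes-free) at the index age.
#' The confidence interval reflects Monte Carlo noise of the simulated
#' cohort (binomial normal approximation); estimation uncertainty of the
#' underlying transition table can be propagated with
#' [bootstrap_lifetime_ci()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param index_age integer index age.
#' @param origin_state `"NORMO"` or `"PRE"`.
#' @param conf_level confidence level of the Monte Carlo interval.
#' @return a one-row `data.frame` with `index_age`, `origin_state`,
#'   `lifetime_risk`, `ci_lo`, `ci_hi`, `n_conditioning`, `unstable`.
#' @export
remaining_lifetime_risk <- function(cohort, index_age, origin_state,
                                    conf_level = 0.95) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  origin_state <- match.arg(origin_state, c("NORMO", "PRE"))
  sel <- .occupies_at(cohort, index_age, origin_state)
  m <- sum(sel)
  if (m == 0L) {
    warning(sprintf("no simulated person occupies %s at age %d; estimate unstable",
                    origin_state, index_age))
    return(data.frame(index_age = index_age, origin_state = origin_state,
                      lifetime_risk = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, n_conditioning = 0L, unstable = TRUE))
  }
  p <- mean(!is.na(cohort$dm_onset[sel]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(p * (1 - p) / m)
  data.frame(index_age = index_age, origin_state = origin_state,
             lifetime_risk = p,
             ci_lo = max(0, p - z * se), ci_hi = min(1, p + z * se),
             n_conditioning = m, unstable = FALSE)
}

#' Expected life years with and without diabetes from a simulated cohort
#'
#' Among people occupying `origin_state` at the index age,
#' `years_without_dm` is the mean number of years from the index age to
#' diabetes onset (or to death/truncation if diabetes never occurs) and
#' `years_with_dm` the mean number of years from diabetes onset to
#' death/truncation (zero for people who never develop diabetes).
#' `prop_with_dm` is the mean over individuals of the per-person fraction
#' of remaining life years spent with diabetes, zeros included; this
#' per-individual convention differs from the ratio of the two means.
#' Survivors at the terminal age are truncated there for year accounting.
#'
#' @inheritParams remaining_lifetime_risk
#' @param origin_state `"NORMO"`, `"PRE"` or `"ANY"` (any living state,
#'   used for prevalence-based cross-checks).
#' @return a one-row `data.frame` with the means, their Monte Carlo 95%
#'   confidence bounds, and `n_conditioning`.
#' @export
life_years <- function(cohort, index_age, origin_state, conf_level = 0.95) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  origin_state <- match.arg(origin_state, c("NORMO", "PRE", "ANY"))
  sel <- .occupies_at(cohort, index_age, origin_state)
  m <- sum(sel)
  if (m == 0L) {
    warning(sprintf("no simulated person occupies %s at age %d; estimate unstable",
                    origin_state, index_age))
    return(data.frame(index_age = index_age, origin_state = origin_state,
                      years_without_dm = NA_real_, years_with_dm = NA_real_,
                      prop_with_dm = NA_real_,
                      yrs_without_lo = NA_real_, yrs_without_hi = NA_real_,
                      yrs_with_lo = NA_real_, yrs_with_hi = NA_real_,
                      n_conditioning = 0L, unstable = TRUE))
  }
  end <- .end_age(cohort)[sel]
  dm <- cohort$dm_onset[sel]
  dm_eff <- pmin(ifelse(is.na(dm), end, dm), end)
  without_i <- pmax(dm_eff - index_age, 0)
  with_i <- (end - index_age) - without_i
  total_i <- end - index_age
  prop_i <- ifelse(total_i > 0, with_i / total_i, 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- function(v) stats::sd(v) / sqrt(m) * z
  data.frame(index_age = index_age, origin_state = origin_state,
             years_without_dm = mean(without_i), years_with_dm = mean(with_i),
             prop_with_dm = mean(prop_i),
             yrs_without_lo = mean(without_i) - ci(without_i),
             yrs_without_hi = mean(without_i) + ci(without_i),
             yrs_with_lo = mean(with_i) - ci(with_i),
             yrs_with_hi = mean(with_i) + ci(with_i),
             n_conditioning = m, unstable = FALSE)
}

#' Combined lifetime estimate (risk and life years)
#'
#' @inheritParams remaining_lifetime_risk
#' @return one-row `data.frame` merging [remaining_lifetime_risk()] and
#'   [life_years()].
#' @export
lifetime_estimate <- function(cohort, index_age, origin_state) {
  risk <- remaining_lifetime_risk(cohort, index_age, origin_state)
  yrs <- life_years(cohort, index_age, origin_state)
  cbind(risk[c("index_age", "origin_state", "lifetime_risk", "ci_lo", "ci_hi",
               "n_conditioning", "unstable")],
        yrs[c("years_without_dm", "years_with_dm", "prop_with_dm")])
}

#' Bootstrap confidence intervals propagating estimation uncertainty
#'
#' Resamples the observed transition counts of an estimated table
#' (per-row multinomial resampling given the at-risk counts), re-simulates a
#' reduced cohort per replicate, and returns percentile intervals for the
#' lifetime risk and life-year quantities.  Rows of the table without
#' observed counts (borrowed fallback rows) are kept fixed.
#'
#' @param table an estimated [transition_table()] carrying `n_at_risk`.
#' @param index_age,origin_state as in [remaining_lifetime_risk()].
#' @param B number of bootstrap replicates (default 200).
#' @param n_rep cohort size per replicate (default 1e5).
#' @param seed integer seed.
#' @param conf_level confidence level.
#' @return a `data.frame` with one row per quantity (`lifetime_risk`,
#'   `years_without_dm`, `years_with_dm`, `prop_with_dm`) and columns
#'   `estimate`, `lo`, `hi`.
#' @export
bootstrap_lifetime_ci <- function(table, index_age, origin_state,
                                  B = 200L, n_rep = 1e5, seed = NULL,
                                  conf_level = 0.95) {
  stopifnot(inherits(table, "transition_table"))
  if (is.null(table$n_at_risk)) {
    stop("table carries no at-risk counts; bootstrap requires an estimated table")
  }
  if (!is.null(seed)) set.seed(seed)
  nA <- length(table$ages)
  draws <- matrix(NA_real_, B, 4,
                  dimnames = list(NULL, c("lifetime_risk", "years_without_dm",
                                          "years_with_dm", "prop_with_dm")))
  for (b in seq_len(B)) {
    Pb <- table$P
    for (ai in seq_len(nA)) {
      for (s in 1:3) {
        nar <- table$n_at_risk[ai, s]
        if (is.na(nar) || nar == 0) next
        cnt <- stats::rmultinom(1, nar, table$P[ai, s, ])
        Pb[ai, s, ] <- cnt / nar
      }
    }
    tb <- transition_table(Pb, sex = table$sex, ages = table$ages)
    coh <- simulate_cohort(tb, n = n_rep, seed = NULL)
    r <- remaining_lifetime_risk(coh, index_age, origin_state)
    y <- life_years(coh, index_age, origin_state)
    draws[b, ] <- c(r$lifetime_risk, y$years_without_dm, y$years_with_dm,
                    y$prop_with_dm)
  }
  alpha <- (1 - conf_level) / 2
  point_coh <- simulate_cohort(table, n = n_rep, seed = NULL)
  pr <- remaining_lifetime_risk(point_coh, index_age, origin_state)
  py <- life_years(point_coh, index_age, origin_state)
  data.frame(
    quantity = colnames(draws),
    estimate = c(pr$lifetime_risk, py$years_without_dm, py$years_with_dm,
                 py$prop_with_dm),
    lo = apply(draws, 2, stats::quantile, probs = alpha, na.rm = TRUE),
    hi = apply(draws, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE),
    row.names = NULL
  )
}

#' Compare simulated and observed short-term cumulative incidence
#'
#' Turns the simulated cohort into fully observed annual histories, computes
#' death-adjusted cumulative incidence curves of progression to diabetes on
#' both sides with the same estimator, and reports the maximum vertical
#' discrepancy per onset-age stratum.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param histories resolved state histories (see [resolve_histories()]).
#' @param origin_state `"PRE"` or `"NORMO"`.
#' @param age_groups numeric cut points for baseline-age strata
#'   (default `c(0, 20, 40, 60, Inf)`).
#' @param min_n_risk discrepancies are measured only over times at which
#'   both curves still have at least this many subjects at risk (short
#'   registry follow-up must not be extrapolated against the simulation's
#'   full horizon); strata with no such common support are skipped with a
#'   warning.
#' @return a `data.frame` with one row per stratum: `stratum`,
#'   `max_discrepancy`, `t_max` (last compared time), `n_observed`,
#'   `n_simulated`, plus the two curves as an attribute `curves`.
#' @export
validate_against_observed <- function(cohort, histories, origin_state = "PRE",
                                      age_groups = c(0, 20, 40, 60, Inf),
                                      min_n_risk = 50L) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  sim_hist <- cohort_as_histories(cohort)
  obs <- cumulative_incidence(histories, origin_state = origin_state,
                              age_groups = age_groups, adjust_death = TRUE)
  sim <- cumulative_incidence(sim_hist, origin_state = origin_state,
                              age_groups = age_groups, adjust_death = TRUE)
  strata <- union(unique(obs$stratum), unique(sim$stratum))
  rows <- list()
  curves <- list()
  for (st in strata) {
    oc <- obs[obs$stratum == st, ]
    sc <- sim[sim$stratum == st, ]
    t_ok <- function(cu) {
      keep <- cu$n_risk >= min_n_risk
      if (!any(keep)) -Inf else max(cu$time[keep])
    }
    t_max <- min(t_ok(oc), t_ok(sc))
    if (nrow(oc) == 0 || nrow(sc) == 0 || !is.finite(t_max)) {
      warning("stratum skipped (insufficient common support): ", st)
      next
    }
    grid <- sort(unique(c(oc$time, sc$time)))
    grid <- grid[grid <= t_max]
    step <- function(cu) stats::approx(c(0, cu$time), c(0, cu$cif),
                                       xout = grid, method = "constant",
                                       rule = 2)$y
    disc <- max(abs(step(oc) - step(sc)))
    rows[[st]] <- data.frame(stratum = st, max_discrepancy = disc,
                             t_max = t_max,
                             n_observed = max(oc$n_risk),
                             n_simulated = max(sc$n_risk))
    curves[[st]] <- list(observed = oc, simulated = sc)
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}

#' Express a simulated cohort as fully observed annual state histories
#'
#' Utility bridging the simulation and the observed-data estimators: each
#' simulated trajectory becomes a history with entry at the cohort start age
#' and complete annual observation to death or truncation.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return a `data.table` in the resolved-history layout of
#'   [resolve_histories()].
#' @export
cohort_as_histories <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  start <- attr(cohort, "start_age")
  sexes <- attr(cohort, "sex")
  # a recorded death age D means entry into DEATH at integer age D, i.e. the
  # death event happened during year D-1; place the continuous death time at
  # D - 0.5 so floor() recovers the transition age used by the estimators
  death_cont <- cohort$death_age - 0.5
  end_cont <- ifelse(is.na(death_cont), attr(cohort, "terminal_age"),
                     death_cont)
  data.table::data.table(
    person_id = sprintf("sim%08d", seq_len(nrow(cohort))),
    sex = if (sexes == "pooled") "F" else sexes,
    birth_year = NA_integer_,
    entry_age = as.numeric(start),
    pre_onset_age = as.numeric(cohort$pre_onset),
    dm_onset_age = as.numeric(cohort$dm_onset),
    death_age = as.numeric(death_cont),
    censor_age = as.numeric(end_cont),
    last_meas_age = as.numeric(ifelse(is.na(death_cont),
                                      attr(cohort, "terminal_age"),
                                      death_cont)),
    # complete trajectories: vital status known over the whole horizon
    vital_end_age = as.numeric(attr(cohort, "terminal_age") + 1L),
    n_measurements = NA_integer_,
    followup_years = as.numeric(end_cont - start)
  )
}
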