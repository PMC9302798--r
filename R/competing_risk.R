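#' Nonparametric cumulative incidence under competing risks
#'
#' Aalen-Johansen-type estimator of the cumulative incidence of a cause-1
#' event in the presence of a competing cause-2 event, with optional
#' delayed entry (left truncation).  At each distinct observed time the
#' all-cause event-free survival is decremented by `(d1 + d2) / n` and the
#' cumulative incidence increased by `S(t-) d1 / n`.  Ties are processed as
#' simultaneous, with events and competing events sharing the at-risk count
#' and censorings leaving the risk set afterwards.  Pointwise confidence
#' bounds use the standard competing-risks variance estimator with a
#' log(-log) transformation.
#'
#' @param time numeric exit times (event, competing event, or censoring).
#' @param status integer: 0 = censored, 1 = event of interest,
#'   2 = competing event.
#' @param entry optional numeric entry times (delayed entry); default all
#'   enter at or before the first time.
#' @param conf_level confidence level for pointwise bounds.
#' @return a `data.frame` with one row per distinct time at which anything
#'   happens: `time`, `n_risk`, `d_event`, `d_competing`, `surv` (all-cause
#'   event-free survival just after `time`), `cif`, `se`, `lo`, `hi`.
#' @export
competing_risk_cif <- function(time, status, entry = NULL,
                               conf_level = 0.95) {
  stopifnot(length(time) == length(status), all(status %in% 0:2))
  if (is.null(entry)) entry <- rep(-Inf, length(time))
  keep <- time >= entry
  time <- time[keep]; status <- status[keep]; entry <- entry[keep]
  if (!length(time)) stop("no subjects at risk")
  ts <- sort(unique(time))
  k <- length(ts)
  n_risk <- d1 <- d2 <- dc <- integer(k)
  for (i in seq_len(k)) {
    t <- ts[i]
    n_risk[i] <- sum(entry <= t & time >= t)
    d1[i] <- sum(time == t & status == 1L)
    d2[i] <- sum(time == t & status == 2L)
    dc[i] <- sum(time == t & status == 0L)
  }
  d <- as.numeric(d1 + d2)
  n_risk <- as.numeric(n_risk)
  S_prev <- c(1, cumprod(1 - d / n_risk))[seq_len(k)]
  inc <- S_prev * d1 / n_risk
  cif <- cumsum(inc)
  surv <- S_prev * (1 - d / n_risk)

  # competing-risks variance (Marubini-Valsecchi / Klein-Moeschberger form)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  var_cif <- numeric(k)
  for (i in seq_len(k)) {
    j <- seq_len(i)
    diff_ <- cif[i] - cif[j]
    t1 <- ifelse(n_risk[j] - d[j] > 0,
                 diff_^2 * d[j] / (n_risk[j] * (n_risk[j] - d[j])), 0)
    t2 <- S_prev[j]^2 * ((n_risk[j] - d1[j]) / n_risk[j]) * d1[j] / n_risk[j]^2
    t3 <- diff_ * S_prev[j] * d1[j] / n_risk[j]^2
    var_cif[i] <- sum(t1) + sum(t2) - 2 * sum(t3)
  }
  se <- sqrt(pmax(var_cif, 0))
  lo <- hi <- rep(NA_real_, k)
  pos <- cif > 0 & cif < 1 & se > 0
  theta <- exp(z * se[pos] / (cif[pos] * log(cif[pos])))
  lo[pos] <- cif[pos]^(1 / theta)
  hi[pos] <- cif[pos]^theta
  lo[!pos] <- cif[!pos]; hi[!pos] <- cif[!pos]
  data.frame(time = ts, n_risk = n_risk, d_event = d1, d_competing = d2,
             surv = surv, cif = cif, se = se,
             lo = pmin(lo, hi), hi = pmax(lo, hi))
}

# exit time and cause for progression-to-diabetes analyses, shared by the
# CIF and modified Kaplan-Meier estimators.  Returns ages on the age
# timescale: event (DM onset, floored), attributable competing death, or
# censoring at the knowledge horizon.
.exit_on_age_scale <- function(h, max_age = 110L) {
  fe <- pmax(floor(h$entry_age), 0)
  pref <- floor(h$pre_onset_age)
  dmf <- floor(h$dm_onset_age)
  dthf <- floor(h$death_age)
  # each exit kind has its own certification: a progression event is
  # certified by the qualifying measurement that detects it (an event dated
  # only by a clinical flag after the last measurement has no matching
  # person-time and is censored instead); a competing death needs vital
  # coverage of its full one-year interval; a censored person leaves at the
  # last age where both processes could still have been observed
  G <- pmin(floor(h$last_meas_age), max_age)
  V <- pmin(floor(.vital_end(h)) - 1L, max_age)
  event <- !is.na(dmf) & dmf <= G
  death_attrib <- !event & !is.na(dthf) & dthf <= V
  exit_age <- ifelse(event, dmf, ifelse(death_attrib, dthf, pmin(G, V)))
  status <- ifelse(event, 1L, ifelse(death_attrib, 2L, 0L))
  list(fe = fe, pref = pref, dmf = dmf, exit_age = exit_age, status = status)
}

#' Short-term cumulative incidence of progression to diabetes
#'
#' Cumulative incidence of progression from the origin state to diabetes,
#' by years since baseline, stratified by baseline age group (and
#' optionally sex).  For progression from prediabetes the baseline is the
#' onset of prediabetes; from normoglycemia it is entry (the first glycemic
#' measurement).  With `adjust_death = TRUE` death before diabetes is a
#' competing event absorbing probability mass (Aalen-Johansen); otherwise
#' death is treated as censoring (one minus Kaplan-Meier), which never
#' yields a smaller estimate.
#'
#' @param histories resolved histories.
#' @param origin_state `"PRE"` or `"NORMO"`.
#' @param age_groups cut points of baseline age strata
#'   (default `c(0, 20, 40, 60, Inf)`).
#' @param adjust_death adjust for the competing risk of death (default TRUE).
#' @param by_sex additionally stratify by sex.
#' @param conf_level confidence level for pointwise bounds.
#' @param max_age administrative horizon on the age scale (default 110).
#' @return a `data.frame` of class `cif_curve` in tidy layout: `stratum`,
#'   `time` (years since baseline), `cif`, `lo`, `hi`, `n_risk`,
#'   `d_event`, `d_competing`; skipped-record counts are attached as
#'   attribute `n_skipped`.
#' @export
cumulative_incidence <- function(histories, origin_state = "PRE",
                                 age_groups = c(0, 20, 40, 60, Inf),
                                 adjust_death = TRUE, by_sex = FALSE,
                                 conf_level = 0.95, max_age = 110L) {
  origin_state <- match.arg(origin_state, c("PRE", "NORMO"))
  h <- data.table::as.data.table(histories)
  ex <- .exit_on_age_scale(h, max_age)
  if (origin_state == "PRE") {
    sel <- !is.na(h$pre_onset_age)
    baseline <- ifelse(sel, pmax(ex$pref, ex$fe), NA_real_)
  } else {
    sel <- (is.na(ex$pref) | ex$pref > ex$fe) & (is.na(ex$dmf) | ex$dmf > ex$fe)
    baseline <- ex$fe
  }
  t_exit <- ex$exit_age - baseline
  ok <- sel & !is.na(t_exit) & t_exit >= 0 &
    !(ex$status == 1L & ex$dmf < baseline)
  n_skipped <- sum(sel, na.rm = TRUE) - sum(ok, na.rm = TRUE)
  status <- ex$status
  if (!adjust_death) status[status == 2L] <- 0L

  grp_lab <- function(a) {
    cut(a, breaks = age_groups, right = FALSE, include.lowest = TRUE)
  }
  strat <- as.character(grp_lab(baseline))
  if (by_sex) strat <- paste(strat, h$sex, sep = "/")
  out <- list()
  for (st in sort(unique(strat[ok]))) {
    i <- which(ok & strat == st)
    cf <- competing_risk_cif(t_exit[i], status[i], conf_level = conf_level)
    out[[st]] <- data.frame(stratum = st, cf[c("time", "cif", "lo", "hi",
                                               "n_risk", "d_event",
                                               "d_competing")])
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "n_skipped") <- n_skipped
  attr(res, "adjusted_for_death") <- adjust_death
  class(res) <- c("cif_curve", class(res))
  res
}

#' Modified Kaplan-Meier lifetime risk with age as the timescale
#'
#' Cumulative-incidence construction of the remaining lifetime risk of
#' diabetes up to the terminal age: persons enter the risk set at the later
#' of the index age and their entry into the origin state (left
#' truncation), the annual hazard of diabetes among those at risk is
#' accumulated, and death before diabetes is a competing event absorbing
#' probability mass,
#' `risk = sum_a h_dm(a) * prod_{b < a} (1 - h_dm(b) - h_death(b))`.
#'
#' For origin `"PRE"` the risk set at age `a` contains persons already in
#' prediabetes and still diabetes-free; for origin `"NORMO"` it contains
#' persons normoglycemic at their risk-set entry who remain diabetes-free
#' (progression through prediabetes keeps them at risk).
#'
#' @param histories resolved histories.
#' @param origin_state `"PRE"` or `"NORMO"`.
#' @param index_age integer index age.
#' @param sex optional stratum (`"M"` or `"F"`).
#' @param max_age terminal age (default 110).
#' @param conf_level confidence level.
#' @return a list with `lifetime_risk`, `se`, `lo`, `hi`, `n_at_entry`
#'   (persons ever at risk), `unstable` flag, and the underlying discrete
#'   hazard table as `hazards`.
#' @export
modified_km_lifetime_risk <- function(histories, origin_state = "PRE",
                                      index_age, sex = NULL,
                                      max_age = 110L, conf_level = 0.95) {
  origin_state <- match.arg(origin_state, c("PRE", "NORMO"))
  h <- data.table::as.data.table(histories)
  if (!is.null(sex)) {
    keep_rows <- which(h[["sex"]] == sex)
    h <- h[keep_rows]
  }
  ex <- .exit_on_age_scale(h, max_age)
  if (origin_state == "PRE") {
    sel <- !is.na(ex$pref)
    entry_rs <- pmax(index_age, ex$pref, ex$fe)
  } else {
    entry_rs <- pmax(index_age, ex$fe)
    sel <- (is.na(ex$pref) | ex$pref > entry_rs) &
      (is.na(ex$dmf) | ex$dmf > entry_rs)
  }
  ok <- which(sel & ex$exit_age >= entry_rs)
  if (!length(ok)) {
    warning("no persons at risk at index age ", index_age, "; estimate unstable")
    return(list(lifetime_risk = NA_real_, se = NA_real_, lo = NA_real_,
                hi = NA_real_, n_at_entry = 0L, unstable = TRUE,
                hazards = NULL))
  }
  cf <- competing_risk_cif(ex$exit_age[ok], ex$status[ok],
                           entry = entry_rs[ok], conf_level = conf_level)
  last <- nrow(cf)
  list(lifetime_risk = cf$cif[last], se = cf$se[last],
       lo = cf$lo[last], hi = cf$hi[last],
       n_at_entry = length(ok), unstable = FALSE, hazards = cf)
}

#' Modified Kaplan-Meier sum from annual probabilities
#'
#' Deterministic building block shared with the birth-cohort extrapolation:
#' given annual probabilities of the event and of competing death over
#' consecutive ages, returns
#' `sum_a p_event(a) * prod_{b < a} (1 - p_event(b) - p_death(b))`.
#'
#' @param p_event,p_death numeric vectors of annual probabilities over
#'   consecutive one-year age intervals.
#' @return the cumulative incidence over the covered ages.
#' @export
mkm_from_probs <- function(p_event, p_death = 0) {
  p_death <- rep_len(p_death, length(p_event))
  stay <- pmax(1 - p_event - p_death, 0)
  S_prev <- c(1, cumprod(stay))[seq_along(p_event)]
  sum(S_prev * p_event)
}
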