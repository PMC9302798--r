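test_that("hand-worked Aalen-Johansen fixture is matched exactly", {
  # events at t=1 and t=2, a competing death at 1.5, censoring at 3 and 4
  cf <- competing_risk_cif(c(1, 2, 1.5, 3, 4), c(1L, 1L, 2L, 0L, 0L))
  expect_equal(cf$cif[cf$time == 1], 0.2)
  expect_equal(cf$cif[cf$time == 1.5], 0.2)
  expect_equal(cf$surv[cf$time == 1.5], 0.6)
  expect_equal(cf$cif[cf$time == 2], 0.2 + 0.6 / 3)  # 0.4
  expect_equal(cf$cif[cf$time == 4], 0.4)
  expect_true(all(diff(cf$cif) >= 0))
})

test_that("without competing deaths the adjusted curve equals 1 - KM", {
  set.seed(41)
  t <- rexp(300, 0.1)
  status <- ifelse(runif(300) < 0.6, 1L, 0L)
  adj <- competing_risk_cif(t, status)
  km <- competing_risk_cif(t, status)     # no status-2 anywhere
  expect_equal(adj$cif, km$cif)
  expect_equal(adj$cif, 1 - adj$surv, tolerance = 1e-12)
})

test_that("cause-specific incidences and survival always sum to one", {
  set.seed(43)
  for (i in 1:5) {
    t <- ceiling(rexp(200, 0.2))
    status <- sample(0:2, 200, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    c1 <- competing_risk_cif(t, status)
    c2 <- competing_risk_cif(t, ifelse(status == 0L, 0L, 3L - status))
    expect_equal(c1$cif + c2$cif + c1$surv, rep(1, nrow(c1)),
                 tolerance = 1e-9)
    # unadjusted (death censored) never lies below the adjusted curve
    un <- competing_risk_cif(t, ifelse(status == 2L, 0L, status))
    grid <- stats::approx(c(0, un$time), c(0, un$cif), xout = c1$time,
                          method = "constant", rule = 2)$y
    expect_true(all(grid - c1$cif >= -1e-9))
  }
})

test_that("our estimator matches the survival package's Aalen-Johansen", {
  skip_if_not_installed("survival")
  set.seed(47)
  t <- ceiling(rexp(500, 0.15))
  status <- sample(0:2, 500, replace = TRUE)
  cf <- competing_risk_cif(t, status)
  f <- survival::survfit(
    survival::Surv(t, factor(status, 0:2, c("cens", "ev", "death"))) ~ 1
  )
  aj <- f$pstate[, which(f$states == "ev")]
  expect_equal(cf$cif, aj[match(cf$time, f$time)], tolerance = 1e-12)
})

test_that("late entrants after the last event leave the curve unchanged", {
  t <- c(2, 3, 5, 6)
  s <- c(1L, 1L, 0L, 0L)
  e <- c(0, 0, 0, 0)
  base <- competing_risk_cif(t, s, e)
  extra <- competing_risk_cif(c(t, 9, 10), c(s, 0L, 0L), c(e, 7, 8))
  expect_equal(extra$cif[extra$time %in% base$time], base$cif)
})

test_that("modified Kaplan-Meier reproduces a two-age hand sum with left truncation", {
  expect_equal(mkm_from_probs(c(0.2, 0.2), c(0.1, 0.1)), 0.34)
  # two waves of ten persons: at ages 70 and 71, hazards .2 (DM) and .1 (death)
  mk_wave <- function(tag, age0) {
    recs <- lapply(1:10, function(i) {
      id <- paste0(tag, i)
      first <- rec(id, age0 + 0.1, "FPG", 6.0)
      if (i <= 2) rbind(first, rec(id, age0 + 0.6, "FPG", 8.0))
      else if (i == 3) rbind(first, rec(id, age0 + 0.6, "death"))
      else rbind(first, rec(id, age0 + 1.1, "FPG", 6.0))  # survivors re-tested
    })
    data.table::rbindlist(recs)
  }
  h <- resolve_histories(rbind(mk_wave("a", 70), mk_wave("b", 71)))
  m <- modified_km_lifetime_risk(h, "PRE", 70)
  expect_equal(m$lifetime_risk, 0.34)
  expect_equal(m$n_at_entry, 20L)
})

test_that("modified KM equals the chain's absorption probability on complete data", {
  tab <- default_truth_transitions("F")
  coh <- simulate_cohort(tab, 30000, seed = 51)
  h <- cohort_as_histories(coh)
  for (ia in c(20, 40)) {
    m <- modified_km_lifetime_risk(h, "NORMO", ia)
    r <- remaining_lifetime_risk(coh, ia, "NORMO")
    expect_equal(m$lifetime_risk, r$lifetime_risk, tolerance = 1e-12)
  }
  # zero-mortality data with a common baseline: the modified KM equals the
  # plain cumulative incidence of progression evaluated at the horizon
  tab0 <- const_table(p_np = 0.02, p_pd = 0.05)
  coh0 <- simulate_cohort(tab0, 20000, seed = 52, start_state = "PRE")
  h0 <- cohort_as_histories(coh0)
  m0 <- modified_km_lifetime_risk(h0, "PRE", 0)
  cif0 <- cumulative_incidence(h0, "PRE", age_groups = c(0, Inf))
  expect_equal(m0$lifetime_risk, max(cif0$cif), tolerance = 1e-9)
})

test_that("short-term cumulative incidence stratifies by baseline age group", {
  cfg <- generator_config(n_persons = 20000, seed = 53)
  h <- resolve_histories(generate_registry(cfg), study_end = 2019)
  cif <- cumulative_incidence(h, "PRE", adjust_death = TRUE)
  expect_s3_class(cif, "cif_curve")
  expect_true(all(c("stratum", "time", "cif", "lo", "hi", "n_risk") %in%
                    names(cif)))
  expect_true(all(cif$cif >= 0 & cif$cif <= 1))
  for (st in unique(cif$stratum)) {
    expect_true(all(diff(cif$cif[cif$stratum == st]) >= 0))
  }
  un <- cumulative_incidence(h, "PRE", adjust_death = FALSE)
  last_adj <- tapply(cif$cif, cif$stratum, max)
  last_un <- tapply(un$cif, un$stratum, max)
  expect_true(all(last_un[names(last_adj)] >= last_adj - 1e-9))
})

test_that("an empty risk set is flagged unstable", {
  h <- resolve_histories(rbind(rec("p", 30, "FPG", 6.0),
                               rec("p", 35, "FPG", 6.0)))
  expect_warning(m <- modified_km_lifetime_risk(h, "PRE", 80), "unstable")
  expect_true(m$unstable)
})
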