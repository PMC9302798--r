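test_that("incidence rate arithmetic", {
  expect_equal(incidence_rate(0, 100), 0)
  expect_equal(round(incidence_rate(5, 250), 1), 20)
  expect_error(incidence_rate(1, 0), "zero person-years")
})

# ten people observed in prediabetes from age 50 to 51: three progress,
# one dies, six remain -> row (0, .6, .3, .1)
test_that("occurrence/exposure row reproduces a hand count", {
  recs <- list()
  for (i in 1:10) {
    id <- sprintf("p%02d", i)
    recs[[id]] <- rbind(
      rec(id, 50.0, "FPG", 6.0),
      if (i <= 3) rec(id, 51.2, "FPG", 8.0)            # progress to DM
      else if (i == 4) rec(id, 50.5, "death")           # die during the year
      else rec(id, 51.2, "FPG", 6.0)                    # remain PRE
    )
  }
  h <- resolve_histories(data.table::rbindlist(recs))
  est <- estimate_transitions(h)
  expect_equal(unname(est$P[51, 2, ]), c(0, 0.6, 0.3, 0.1))
  expect_equal(est$n_at_risk[51, 2], 9L)        # progression risk set
  expect_equal(est$n_at_risk_death[51, 2], 10L) # vital risk set
})

test_that("event-free fully observed histories give diagonal rows", {
  recs <- data.table::rbindlist(lapply(1:5, function(i) {
    id <- sprintf("s%d", i)
    data.table::rbindlist(lapply(40:45, function(a) rec(id, a + 0.5, "FPG", 5.0)))
  }))
  est <- estimate_transitions(resolve_histories(recs))
  for (a in 41:44) expect_equal(est$P[a + 1, 1, 1], 1)
  expect_true(all(est$n_trans[, , 4] == 0))
})

test_that("pooled counts are the sum of sex-stratum counts", {
  cfg <- generator_config(n_persons = 8000, seed = 23)
  h <- resolve_histories(generate_registry(cfg), study_end = 2019)
  ef <- estimate_transitions(h, "F")
  em <- estimate_transitions(h, "M")
  ep <- estimate_transitions(h, "pooled")
  expect_equal(ep$n_trans, ef$n_trans + em$n_trans)
  expect_equal(ep$n_at_risk, ef$n_at_risk + em$n_at_risk)
  expect_equal(ep$n_at_risk_death, ef$n_at_risk_death + em$n_at_risk_death)
})

test_that("period windows partition the transition counts", {
  cfg <- generator_config(n_persons = 6000, seed = 29)
  h <- resolve_histories(generate_registry(cfg), study_end = 2019)
  e1 <- estimate_transitions(h, period_window = c(2001, 2009))
  e2 <- estimate_transitions(h, period_window = c(2010, 2019))
  eall <- estimate_transitions(h, period_window = c(2001, 2019))
  expect_equal(e1$n_trans + e2$n_trans, eall$n_trans)
  expect_error(estimate_transitions(h[0], "F"), "stratum")
})

test_that("zero-at-risk ages borrow the nearest populated row", {
  recs <- data.table::rbindlist(lapply(1:20, function(i) {
    id <- sprintf("b%d", i)
    rbind(rec(id, 50.1, "FPG", 5.0), rec(id, 55.4, "FPG", 5.0))
  }))
  est <- estimate_transitions(resolve_histories(recs))
  expect_true(est$borrowed[11, 1])   # age 10: no one observed
  expect_equal(est$P[11, 1, 1], 1)   # borrowed from the event-free ages
  expect_false(any(est$borrowed[52:55, 1]))
})

test_that("crude incidence accrues person-time from state onset and is split-invariant", {
  # one person: PRE detected at 50, DM at 60 -> 10 PY, 1 event
  whole <- rbind(rec("w", 50, "FPG", 6.0), rec("w", 60, "FPG", 8.0))
  ci_w <- crude_incidence(resolve_histories(whole), "PRE", "DM")
  expect_equal(ci_w$person_years, 10)
  expect_equal(ci_w$events, 1)
  # the same follow-up handed over between two record streams
  split <- rbind(rec("a", 50, "FPG", 6.0), rec("a", 55, "FPG", 6.0),
                 rec("b", 55, "FPG", 6.0), rec("b", 60, "FPG", 8.0))
  hs <- resolve_histories(split)
  ci_s <- crude_incidence(hs, "PRE", "DM")
  expect_equal(ci_s$person_years, ci_w$person_years)
  expect_equal(ci_s$events, ci_w$events)
  expect_equal(ci_s$rate, ci_w$rate)
  expect_error(crude_incidence(hs, "DM", "PRE"), "severity")
})

test_that("estimator consistency: cellwise error shrinks with sample size", {
  err <- sapply(c(10000, 100000), function(n) {
    cfg <- generator_config(n_persons = n, seed = 31,
                            testing_schedule = "annual")
    h <- resolve_histories(generate_registry(cfg), study_end = 2019)
    est <- estimate_transitions(h, "F")
    truth <- export_truth(cfg, "F")
    idx <- which(est$n_at_risk > 0.005 * n, arr.ind = TRUE)
    cells <- rbind(cbind(idx, 2L), cbind(idx, 3L))
    colnames(cells) <- NULL
    mean(abs(est$P[cells[, c(1, 2, 3)]] - truth$P[cells[, c(1, 2, 3)]]))
  })
  expect_lt(err[2], err[1])
})
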