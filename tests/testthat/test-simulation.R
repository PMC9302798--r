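test_that("simulation is reproducible and rejects bad inputs", {
  tab <- default_truth_transitions("F")
  c1 <- simulate_cohort(tab, 500, seed = 4)
  c2 <- simulate_cohort(tab, 500, seed = 4)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  bad <- tab
  bad$P[30, 2, 2] <- bad$P[30, 2, 2] * 0.5
  expect_error(simulate_cohort(bad, 10, seed = 1), "non-stochastic row")
  expect_error(simulate_cohort(tab, 10, seed = 1, start_state = "DEATH"),
               "DEATH")
})

test_that("certain death empties the cohort after one cycle", {
  tab <- const_table(q_n = 1, q_p = 1, q_d = 1)
  coh <- simulate_cohort(tab, 1000, seed = 5, start_age = 30)
  expect_true(all(coh$death_age == 31L))
  r <- remaining_lifetime_risk(coh, 30, "NORMO")
  expect_equal(r$lifetime_risk, 0)
  expect_equal(r$n_conditioning, 1000L)
})

test_that("constant competing hazards reach the geometric absorption probability", {
  # from PRE: stay .7, DM .2, death .1 each year -> eventual DM = 2/3
  tab <- const_table(p_pd = 0.2, q_p = 0.1)
  coh <- simulate_cohort(tab, 100000, seed = 6, start_state = "PRE")
  p <- mean(!is.na(coh$dm_onset))
  expect_lt(abs(p - 2 / 3), 3 * sqrt(2 / 3 * (1 / 3) / 100000))
})

test_that("simulated risk and life years match the matrix-propagation oracle", {
  tab <- default_truth_transitions("F")
  coh <- simulate_cohort(tab, 100000, seed = 7)
  for (org in c("PRE", "NORMO")) {
    for (ia in c(20L, 40L, 60L)) {
      o <- propagate_oracle(tab, ia, org)
      r <- remaining_lifetime_risk(coh, ia, org)
      y <- life_years(coh, ia, org)
      m <- r$n_conditioning
      expect_lt(abs(r$lifetime_risk - o$risk),
                3 * sqrt(o$risk * (1 - o$risk) / m))
      # conditioning redistributes the oracle's unconditional occupancy;
      # bound the year comparisons by 3 empirical Monte Carlo SEs
      se_without <- (y$yrs_without_hi - y$yrs_without_lo) / (2 * 1.96)
      se_with <- (y$yrs_with_hi - y$yrs_with_lo) / (2 * 1.96)
      oc <- propagate_oracle(tab, ia, org)
      expect_lt(abs(y$years_without_dm - oc$years_without), 3 * se_without)
      expect_lt(abs(y$years_with_dm - oc$years_with), 3 * se_with)
      # alive years split exactly into the two parts
      sel <- liferisk:::.occupies_at(coh, ia, org)
      end <- ifelse(is.na(coh$death_age), 110L, coh$death_age)
      expect_equal(y$years_without_dm + y$years_with_dm, mean(end[sel] - ia),
                   tolerance = 1e-9)
    }
  }
})

test_that("lifetime risk declines with index age and PRE dominates NORMO", {
  tab <- default_truth_transitions("F")
  coh <- simulate_cohort(tab, 50000, seed = 8)
  risks <- sapply(c(20, 40, 60), function(ia) {
    remaining_lifetime_risk(coh, ia, "PRE")$lifetime_risk
  })
  expect_true(all(diff(risks) < 0))
  o <- sapply(c(20, 40, 60), function(ia) propagate_oracle(tab, ia, "PRE")$risk)
  expect_true(all(diff(o) < 0))
  for (ia in c(20, 40, 60)) {
    expect_gte(remaining_lifetime_risk(coh, ia, "PRE")$lifetime_risk,
               remaining_lifetime_risk(coh, ia, "NORMO")$lifetime_risk)
  }
})

test_that("life-year accounting on deterministic trajectories", {
  # diabetes at 60, death at 70, index 60 -> ten years with diabetes
  coh <- manual_cohort(pre = rep(55L, 4), dm = rep(60L, 4),
                       death = rep(70L, 4))
  y <- life_years(coh, 60, "ANY")
  expect_equal(y$years_with_dm, 10)
  expect_equal(y$years_without_dm, 0)
  # per-individual proportion differs from the ratio of mean year totals
  two <- manual_cohort(pre = c(55L, NA), dm = c(60L, NA),
                       death = c(70L, 60L))
  y2 <- life_years(two, 50, "ANY")
  expect_equal(y2$prop_with_dm, mean(c(10 / 20, 0)))
  ratio <- y2$years_with_dm / (y2$years_with_dm + y2$years_without_dm)
  expect_false(isTRUE(all.equal(y2$prop_with_dm, ratio)))
})

test_that("empty conditioning sets are flagged unstable", {
  coh <- manual_cohort(pre = c(NA, NA), dm = c(NA, NA), death = c(50L, 55L))
  expect_warning(r <- remaining_lifetime_risk(coh, 60, "PRE"), "unstable")
  expect_true(r$unstable)
})

test_that("bootstrap intervals bracket the point estimate", {
  cfg <- generator_config(n_persons = 5000, seed = 33)
  h <- resolve_histories(generate_registry(cfg), study_end = 2019)
  est <- estimate_transitions(h)
  ci <- bootstrap_lifetime_ci(est, 40, "PRE", B = 15L, n_rep = 5000,
                              seed = 34)
  expect_true(all(ci$lo <= ci$hi))
  expect_true(all(ci$estimate >= ci$lo - 0.08 & ci$estimate <= ci$hi + 0.08))
})

test_that("predicted-vs-observed validation flags a doubled hazard", {
  cfg <- generator_config(n_persons = 30000, seed = 35,
                          testing_schedule = "annual")
  h <- resolve_histories(generate_registry(cfg), study_end = 2019)
  est <- estimate_transitions(h)
  coh <- simulate_cohort(est, 100000, seed = 36)
  ok <- suppressWarnings(validate_against_observed(coh, h, "PRE",
                                                   min_n_risk = 1000L))
  expect_gt(nrow(ok), 0)
  expect_true(all(ok$max_discrepancy < 0.02))
  # identical inputs agree exactly
  hs <- cohort_as_histories(coh)
  same <- suppressWarnings(validate_against_observed(coh, hs, "PRE"))
  expect_true(all(same$max_discrepancy < 1e-12))
  # doubling the PRE->DM hazard is detected
  bad <- est
  extra <- pmin(bad$P[, 2, 3], bad$P[, 2, 2])
  bad$P[, 2, 3] <- bad$P[, 2, 3] + extra
  bad$P[, 2, 2] <- bad$P[, 2, 2] - extra
  coh_bad <- simulate_cohort(bad, 100000, seed = 37)
  flag <- suppressWarnings(validate_against_observed(coh_bad, h, "PRE",
                                                     min_n_risk = 1000L))
  expect_gt(max(flag$max_discrepancy), 0.04)
})
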