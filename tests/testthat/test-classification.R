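test_that("measurements classify into ADA bands", {
  cases <- list(
    list("FPG", 5.5, "NORMO"), list("FPG", 5.6, "PRE"), list("FPG", 6.0, "PRE"),
    list("FPG", 6.99, "PRE"), list("FPG", 7.0, "DM"),
    list("HbA1c", 38.9, "NORMO"), list("HbA1c", 39, "PRE"),
    list("HbA1c", 47.9, "PRE"), list("HbA1c", 48, "DM"),
    list("OGTT2h", 7.7, "NORMO"), list("OGTT2h", 7.8, "PRE"),
    list("OGTT2h", 11.1, "DM"),
    list("RPG", 25, "NORMO")  # random glucose never yields PRE/DM alone
  )
  for (cs in cases) {
    expect_identical(classify_measurement(cs[[1]], cs[[2]]), cs[[3]])
  }
  expect_error(classify_measurement("FPG", -1), "non-negative")
  expect_error(classify_measurement("CRP", 3), "unknown")
  expect_error(classify_measurement("FPG", "high"), "numeric")
})

test_that("inpatient FPG and gestational-window records are excluded, idempotently", {
  r <- rbind(
    rec("a", 50, "FPG", 6.0, inpatient = TRUE),
    rec("a", 51, "HbA1c", 40, inpatient = TRUE),   # only FPG is excluded when inpatient
    rec("a", 52, "HbA1c", 41, gestational_week = 30L),
    rec("a", 53, "HbA1c", 42, gestational_week = 20L),
    rec("a", 54, "FPG", 6.1),
    rec("a", 55, "dx_code")
  )
  out <- apply_exclusions(r)
  expect_identical(out$event_age, c(51, 53, 54, 55))
  expect_identical(apply_exclusions(out), out)
})

test_that("diabetes criteria resolve onset ages, including the insulin rule", {
  r30 <- rbind(rec("p", 50, "FPG", 5.0),
               rec("p", 55, "insulin_episode", insulin_days = 30L))
  h <- resolve_state_history(r30)
  expect_equal(h$dm_onset_age, 55)
  r14 <- rbind(rec("p", 50, "FPG", 5.0),
               rec("p", 55, "insulin_episode", insulin_days = 14L))
  expect_true(is.na(resolve_state_history(r14)$dm_onset_age))
  # a drug flag alone also identifies diabetes
  rdrug <- rbind(rec("p", 48, "HbA1c", 30),
                 rec("p", 52, "noninsulin_drug"))
  expect_equal(resolve_state_history(rdrug)$dm_onset_age, 52)
})

test_that("states never revert and prediabetes before diabetes wins ties by severity", {
  r <- rbind(rec("p", 50, "FPG", 6.0),    # PRE
             rec("p", 52, "FPG", 5.0))    # back in NORMO band
  h <- resolve_state_history(r)
  expect_equal(h$pre_onset_age, 50)
  sq <- state_sequence(h)
  expect_identical(sq$state[sq$age == 52], "PRE")
  # PRE-band evidence at the same age as DM evidence resolves to DM
  r2 <- rbind(rec("p", 50, "FPG", 6.0), rec("p", 50, "HbA1c", 50))
  h2 <- resolve_state_history(r2)
  expect_equal(h2$dm_onset_age, 50)
  expect_true(is.na(h2$pre_onset_age))
})

test_that("prediabetes definition changes PRE onsets but never DM onsets", {
  r <- rbind(rec("p", 50, "HbA1c", 40),   # PRE by HbA1c only
             rec("p", 52, "FPG", 5.0),
             rec("p", 60, "FPG", 8.0))    # DM
  h_any <- resolve_state_history(r, "any")
  h_fpg <- resolve_state_history(r, "fpg_only")
  h_a1c <- resolve_state_history(r, "hba1c_only")
  expect_equal(h_any$pre_onset_age, 50)
  expect_true(is.na(h_fpg$pre_onset_age))
  expect_equal(h_a1c$pre_onset_age, 50)
  expect_equal(h_any$dm_onset_age, 60)
  expect_equal(h_fpg$dm_onset_age, 60)
  expect_equal(h_a1c$dm_onset_age, 60)
})

test_that("single-person resolution validates its input", {
  expect_error(resolve_state_history(rec("p", 50, "FPG", 6)[0]), "empty")
  two <- rbind(rec("a", 50, "FPG", 6), rec("b", 51, "FPG", 6))
  expect_error(resolve_state_history(two), "more than one person")
  dd <- rbind(rec("p", 50, "FPG", 6), rec("p", 60, "death"),
              rec("p", 61, "death"))
  expect_error(resolve_histories(dd), "death record")
})

test_that("random-glucose-only persons do not enter the cohort", {
  r <- rbind(rec("x", 50, "RPG", 8), rec("y", 50, "FPG", 6))
  h <- resolve_histories(r)
  expect_identical(h$person_id, "y")
})

test_that("cohort filtering by follow-up and entry age", {
  set.seed(1)
  h <- data.table::data.table(
    person_id = letters[1:10], followup_years = c(6, 7, 1, 2, 8, 0, 3, 9, 4, 2),
    entry_age = c(25, 15, 30, 40, 50, 10, 22, 35, 18, 60)
  )
  expect_equal(nrow(filter_cohort(h, min_followup = 5)), 4)
  expect_identical(filter_cohort(h, 0, 0), h)
  expect_equal(nrow(filter_cohort(h, 5, 20)), 3)
  expect_error(filter_cohort(h, -1, 0), "non-negative")
})

test_that("resolved histories round-trip through CSV", {
  r <- rbind(rec("p", 50.2, "FPG", 6.0), rec("p", 55.8, "FPG", 8.0),
             rec("p", 60.1, "death"))
  h <- resolve_histories(r, study_end = 2019)
  path <- withr::local_tempfile(fileext = ".csv")
  write_histories(h, path)
  h2 <- read_histories(path)
  expect_equal(as.data.frame(h2), as.data.frame(h))
})
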