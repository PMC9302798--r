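test_that("generator configuration is validated", {
  expect_error(generator_config(n_persons = 0), "at least 1")
  expect_error(generator_config(n_persons = 10, max_age = 120), "110")
  expect_error(generator_config(n_persons = 10, sex_ratio = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(
    n_persons = 10,
    entry_age_distribution = list(name = "gamma", shape = 2)
  ), "unknown entry age distribution")
  expect_error(generator_config(
    n_persons = 10, measurement_mix = c(FPG = 0.5, HbA1c = 0.2)
  ), "sum to 1")
})

test_that("same configuration and seed give identical registries", {
  cfg <- generator_config(n_persons = 500, seed = 9L)
  r1 <- generate_registry(cfg)
  r2 <- generate_registry(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- generate_registry(generator_config(n_persons = 500, seed = 10L))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("latent trajectories never revert and respect onset ordering", {
  cfg <- generator_config(n_persons = 5000, seed = 3L)
  lat <- attr(generate_registry(cfg), "latent")
  both <- !is.na(lat$latent_pre) & !is.na(lat$latent_dm)
  expect_true(all(lat$latent_pre[both] < lat$latent_dm[both]))
  dm_dth <- !is.na(lat$latent_dm) & !is.na(lat$latent_death)
  expect_true(all(lat$latent_dm[dm_dth] <= lat$latent_death[dm_dth]))
})

test_that("exported truth matches generation and degenerate dynamics are inert", {
  cfg <- generator_config(n_persons = 10)
  tab <- export_truth(cfg, "F")
  expect_s3_class(tab, "transition_table")
  expect_equal(apply(tab$P, c(1, 2), sum), matrix(1, 111, 4),
               ignore_attr = TRUE, tolerance = 1e-12)
  # identity dynamics: nobody transitions, nobody dies
  idt <- const_table()
  cfg0 <- generator_config(n_persons = 2000, seed = 5, truth_transitions = idt)
  lat0 <- attr(generate_registry(cfg0), "latent")
  expect_true(all(is.na(lat0$latent_pre)))
  expect_true(all(is.na(lat0$latent_dm)))
  expect_true(all(is.na(lat0$latent_death)))
  expect_true(all(diag(idt$P[1, , ]) == 1))
})

test_that("observed single-measurement fraction matches the configured 0.212", {
  cfg <- generator_config(n_persons = 30000, seed = 11L)
  reg <- generate_registry(cfg)
  meas <- reg[reg$record_kind %in% c("FPG", "HbA1c", "OGTT2h", "RPG")]
  counts <- table(meas$person_id)
  frac <- mean(counts == 1L)
  se <- sqrt(0.212 * 0.788 / length(counts))
  expect_lt(abs(frac - 0.212), 3 * se)
})

test_that("latent annual PRE->DM frequency matches a configured 0.04 per year", {
  tab <- const_table(p_np = 0.03, p_pd = 0.04, q_n = 0.002, q_p = 0.002,
                     q_d = 0.004, terminal_death = TRUE)
  cfg <- generator_config(n_persons = 50000, seed = 13L,
                          truth_transitions = tab)
  lat <- attr(generate_registry(cfg), "latent")
  for (a in c(30L, 50L, 70L)) {
    in_pre <- !is.na(lat$latent_pre) & lat$latent_pre <= a &
      (is.na(lat$latent_dm) | lat$latent_dm > a) &
      (is.na(lat$latent_death) | lat$latent_death > a)
    n <- sum(in_pre)
    expect_gt(n, 500)
    f <- sum(lat$latent_dm[in_pre] == a + 1L, na.rm = TRUE) / n
    expect_lt(abs(f - 0.04), 3 * sqrt(0.04 * 0.96 / n))
  }
})

test_that("latent death ages reproduce the truth survival curve", {
  cfg <- generator_config(n_persons = 50000, seed = 17L)
  lat <- attr(generate_registry(cfg), "latent")
  for (sx in c("F", "M")) {
    truth <- export_truth(cfg, sx)
    o <- propagate_oracle(truth, 0L, "NORMO")
    cdf_truth <- o$occupancy[, 4] + o$occupancy[, 5]  # dead by age a at row a+1
    d <- lat$latent_death[lat$sex == sx]
    n <- length(d)
    for (a in seq(10, 100, by = 10)) {
      emp <- mean(!is.na(d) & d <= a)
      th <- cdf_truth[a + 1]
      tol <- 3 * sqrt(max(th * (1 - th), 1e-6) / n)
      expect_lt(abs(emp - th), tol + 1e-12)
    }
  }
})

test_that("registry CSV round-trips", {
  cfg <- generator_config(n_persons = 200, seed = 2L)
  reg <- generate_registry(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, path)
  back <- read_registry(path)
  expected <- as.data.frame(reg)
  attr(expected, "latent") <- NULL  # diagnostic attribute is not serialised
  expect_equal(as.data.frame(back), expected, tolerance = 1e-12)
})
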