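# Matrix-propagation oracle for the four-state chain, independent of the
# package's Monte Carlo engine.  Tracks (NORMO, PRE, DM, dead-after-DM,
# dead-without-DM) occupancy from an index age and returns eventual-diabetes
# probability, expected alive years with/without diabetes (annual counting,
# truncation at the terminal age), and the occupancy path.
propagate_oracle <- function(table, index_age, origin) {
  st <- c(NORMO = 1L, PRE = 2L, DM = 3L)[[origin]]
  ages <- table$ages
  terminal <- max(ages)
  v <- numeric(5)
  v[st] <- 1
  yrs_without <- yrs_with <- 0
  occ <- matrix(NA_real_, nrow = terminal - index_age + 1, ncol = 5)
  occ[1, ] <- v
  for (a in index_age:(terminal - 1L)) {
    P <- table$P[match(a, ages), , ]
    yrs_without <- yrs_without + v[1] + v[2]
    yrs_with <- yrs_with + v[3]
    nv <- numeric(5)
    nv[1] <- v[1] * P[1, 1]
    nv[2] <- v[1] * P[1, 2] + v[2] * P[2, 2]
    nv[3] <- v[1] * P[1, 3] + v[2] * P[2, 3] + v[3] * P[3, 3]
    nv[4] <- v[4] + v[3] * P[3, 4]
    nv[5] <- v[5] + v[1] * P[1, 4] + v[2] * P[2, 4]
    v <- nv
    occ[a - index_age + 2, ] <- v
  }
  list(risk = v[3] + v[4], years_without = yrs_without, years_with = yrs_with,
       occupancy = occ)
}

# Age-specific diabetes prevalence among the living implied by the chain,
# starting everyone in NORMO at age 0.
oracle_prevalence <- function(table) {
  o <- propagate_oracle(table, 0L, "NORMO")
  occ <- o$occupancy
  alive <- occ[, 1] + occ[, 2] + occ[, 3]
  ifelse(alive > 0, occ[, 3] / alive, NA_real_)
}

# Constant-dynamics table on ages 0..110 (terminal row left as given; no
# forced terminal death unless requested).
const_table <- function(p_np = 0, p_nd = 0, p_pd = 0,
                        q_n = 0, q_p = 0, q_d = 0, sex = "pooled",
                        terminal_death = FALSE) {
  tab <- transition_table_from_rates(p_np, p_nd, p_pd, q_n, q_p, q_d,
                                     ages = 0:110, sex = sex)
  if (terminal_death) {
    last <- length(tab$ages)
    for (s in 1:3) {
      tab$P[last, s, ] <- 0
      tab$P[last, s, 4] <- 1
    }
  }
  tab
}

# Hand-built simulated_cohort from onset vectors (for deterministic
# year-accounting tests).
manual_cohort <- function(pre, dm, death, start_age = 0L, terminal = 110L,
                          sex = "pooled") {
  out <- data.table::data.table(pre_onset = as.integer(pre),
                                dm_onset = as.integer(dm),
                                death_age = as.integer(death))
  data.table::setattr(out, "start_age", as.integer(start_age))
  data.table::setattr(out, "terminal_age", as.integer(terminal))
  data.table::setattr(out, "sex", sex)
  data.table::setattr(out, "seed", NULL)
  data.table::setattr(out, "class", c("simulated_cohort", class(out)))
  out
}

# One registry record row.
rec <- function(person_id, event_age, record_kind, value = NA_real_,
                sex = "F", birth_year = 1960L, inpatient = FALSE,
                gestational_week = NA_integer_, insulin_days = NA_integer_) {
  data.table::data.table(person_id = person_id, sex = sex,
                         birth_year = birth_year, event_age = event_age,
                         record_kind = record_kind, value = value,
                         inpatient = inpatient,
                         gestational_week = gestational_week,
                         insulin_days = insulin_days)
}
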