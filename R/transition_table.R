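#' Age- and sex-specific one-year transition probability table
#'
#' A `transition_table` holds, for each integer age `a` in `ages`, a 4x4
#' row-stochastic matrix `P[a, s, s']` giving the probability of occupying
#' state `s'` at age `a + 1` conditional on occupying `s` at age `a`.
#' States are ordered NORMO, PRE, DM, DEATH.  Structurally forbidden
#' transitions (any reversion in severity among living states, and
#' DEATH to anything but DEATH) are exactly zero.
#'
#' @param P numeric array of dimension `c(length(ages), 4, 4)`.
#' @param n_trans optional integer array of the same shape with observed
#'   transition counts.
#' @param n_at_risk optional integer matrix `length(ages) x 4` of at-risk
#'   counts by age and origin state.
#' @param sex one of `"M"`, `"F"`, `"pooled"`.
#' @param ages integer vector of ages the rows refer to (default 0:110).
#' @param borrowed optional logical matrix `length(ages) x 4`; `TRUE` where a
#'   row was borrowed from the nearest populated age (zero at-risk fallback).
#' @return an object of class `transition_table`.
#' @seealso [estimate_transitions()], [simulate_cohort()],
#'   [substitute_mortality()]
#' @export
transition_table <- function(P, n_trans = NULL, n_at_risk = NULL,
                             sex = "pooled", ages = 0:110, borrowed = NULL) {
  stopifnot(is.array(P), length(dim(P)) == 3L)
  dimnames(P) <- list(ages, state_levels(), state_levels())
  x <- structure(
    list(P = P, n_trans = n_trans, n_at_risk = n_at_risk,
         sex = match.arg(sex, c("M", "F", "pooled")),
         ages = as.integer(ages), borrowed = borrowed),
    class = "transition_table"
  )
  validate_transition_table(x)
  x
}

#' Structurally allowed transitions of the illness-death model
#'
#' @return a 4x4 logical matrix; `TRUE` where a one-year transition is
#'   permitted (no reversion; DM and DEATH absorbing in severity).
#' @export
allowed_transitions <- function() {
  m <- matrix(FALSE, 4, 4, dimnames = list(state_levels(), state_levels()))
  m["NORMO", ] <- TRUE
  m["PRE", c("PRE", "DM", "DEATH")] <- TRUE
  m["DM", c("DM", "DEATH")] <- TRUE
  m["DEATH", "DEATH"] <- TRUE
  m
}

#' @rdname transition_table
#' @param x a `transition_table`.
#' @param tol numeric tolerance for row-sum checks.
#' @export
validate_transition_table <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "transition_table"))
  P <- x$P
  if (!identical(dim(P)[2:3], c(4L, 4L)) || dim(P)[1] != length(x$ages)) {
    stop("P must be a length(ages) x 4 x 4 array")
  }
  if (any(P < -tol | P > 1 + tol)) stop("transition probabilities outside [0, 1]")
  rs <- apply(P, c(1, 2), sum)
  if (any(abs(rs - 1) > tol)) {
    bad <- which(abs(rs - 1) > tol, arr.ind = TRUE)[1, ]
    stop(sprintf("row does not sum to 1 at age %s, state %s",
                 x$ages[bad[1]], state_levels()[bad[2]]))
  }
  forb <- !allowed_transitions()
  for (s in 1:4) for (t in 1:4) {
    if (forb[s, t] && any(abs(P[, s, t]) > tol)) {
      stop(sprintf("forbidden transition %s -> %s has positive probability",
                   state_levels()[s], state_levels()[t]))
    }
  }
  invisible(x)
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("One-year transition table (%s), ages %d-%d\n",
              x$sex, min(x$ages), max(x$ages)))
  if (!is.null(x$n_at_risk)) {
    cat(sprintf("  total observed transitions: %s\n",
                format(sum(x$n_at_risk), big.mark = ",")))
  }
  if (!is.null(x$borrowed) && any(x$borrowed)) {
    cat(sprintf("  rows borrowed from nearest populated age: %d\n",
                sum(x$borrowed)))
  }
  mid <- x$ages[which.min(abs(x$ages - 60))]
  cat(sprintf("  P at age %d:\n", mid))
  print(round(x$P[as.character(mid), , ], 4))
  invisible(x)
}

#' Build a transition table from per-age hazard-like annual probabilities
#'
#' Convenience constructor used for ground-truth dynamics: supply annual
#' probabilities of the allowed off-diagonal moves and the diagonal is the
#' remainder.  If the off-diagonal probabilities of a row exceed 1 they are
#' rescaled proportionally so the row stays stochastic.
#'
#' @param p_normo_pre,p_normo_dm annual probabilities NORMO->PRE, NORMO->DM.
#' @param q_normo,q_pre,q_dm annual death probabilities from each living state.
#' @param p_pre_dm annual probability PRE->DM.
#' @param ages integer ages (default 0:110).
#' @param sex stratum label.
#' @return a `transition_table`.
#' @export
transition_table_from_rates <- function(p_normo_pre, p_normo_dm, p_pre_dm,
                                        q_normo, q_pre, q_dm,
                                        ages = 0:110, sex = "pooled") {
  nA <- length(ages)
  rec <- function(v) rep_len(v, nA)
  p_np <- rec(p_normo_pre); p_nd <- rec(p_normo_dm); p_pd <- rec(p_pre_dm)
  qn <- rec(q_normo); qp <- rec(q_pre); qd <- rec(q_dm)
  P <- array(0, dim = c(nA, 4, 4))
  row_fill <- function(parts) {
    # parts: matrix nA x k of off-diagonal probabilities; rescale if sum > 1
    tot <- rowSums(parts)
    over <- tot > 1
    if (any(over)) parts[over, ] <- parts[over, , drop = FALSE] / tot[over]
    parts
  }
  np <- row_fill(cbind(p_np, p_nd, qn))
  P[, 1, 2] <- np[, 1]; P[, 1, 3] <- np[, 2]; P[, 1, 4] <- np[, 3]
  P[, 1, 1] <- 1 - rowSums(np)
  pp <- row_fill(cbind(p_pd, qp))
  P[, 2, 3] <- pp[, 1]; P[, 2, 4] <- pp[, 2]
  P[, 2, 2] <- 1 - rowSums(pp)
  dd <- row_fill(cbind(qd))
  P[, 3, 4] <- dd[, 1]; P[, 3, 3] <- 1 - dd[, 1]
  P[, 4, 4] <- 1
  transition_table(P, sex = sex, ages = ages)
}

#' Plausible default ground-truth dynamics for the synthetic registry
#'
#' Age-increasing incidence of prediabetes and diabetes and Gompertz-type
#' mortality with state-specific multipliers, separately for women and men.
#' Death is certain in the final cycle (age 110) so every latent trajectory
#' terminates within the modelled horizon.  These are the study conditions
#' used throughout the package's tests and examples; see the methods
#' vignette for the rationale behind each number.
#'
#' @param sex `"F"`, `"M"` or `"pooled"` (pooled averages the two).
#' @param ages integer ages (default 0:110).
#' @return a `transition_table`.
#' @export
default_truth_transitions <- function(sex = c("F", "M", "pooled"),
                                      ages = 0:110) {
  sex <- match.arg(sex)
  if (sex == "pooled") {
    f <- default_truth_transitions("F", ages)$P
    m <- default_truth_transitions("M", ages)$P
    return(transition_table((f + m) / 2, sex = "pooled", ages = ages))
  }
  a <- ages
  mort_mult <- if (sex == "M") 1.6 else 1.0
  inc_mult <- if (sex == "M") 1.1 else 1.0
  q0 <- pmin(2e-5 * exp(0.1 * a) * mort_mult, 1)
  tab <- transition_table_from_rates(
    p_normo_pre = (0.002 + 0.00055 * a) * inc_mult,
    p_normo_dm  = (0.0004 + 0.00008 * a) * inc_mult,
    p_pre_dm    = (0.035 + 0.0003 * a) * inc_mult,
    q_normo = q0,
    q_pre   = pmin(1.15 * q0, 1),
    q_dm    = pmin(1.8 * q0, 1),
    ages = ages, sex = sex
  )
  # certain death in the final cycle: trajectories end by age 111
  last <- length(ages)
  for (s in 1:3) {
    tab$P[last, s, ] <- 0
    tab$P[last, s, 4] <- 1
  }
  tab
}

#' Replace the death column of a transition table
#'
#' Substitutes per-age, per-state annual death probabilities (for example
#' those of another population) into a table, redistributing the surviving
#' probability mass across the non-death destinations proportionally to
#' their original conditional shares, so every row remains stochastic.
#'
#' @param table a `transition_table`.
#' @param death_probs numeric matrix `length(ages) x 3` of replacement death
#'   probabilities for origin states NORMO, PRE, DM (a vector is recycled
#'   across the three states; a single `transition_table` may also be given,
#'   in which case its death column is used).
#' @return a `transition_table` with the death column replaced.
#' @export
substitute_mortality <- function(table, death_probs) {
  stopifnot(inherits(table, "transition_table"))
  nA <- length(table$ages)
  if (inherits(death_probs, "transition_table")) {
    stopifnot(identical(death_probs$ages, table$ages))
    death_probs <- death_probs$P[, 1:3, 4]
  }
  if (is.vector(death_probs)) {
    death_probs <- if (length(death_probs) == 3L) {
      matrix(death_probs, nA, 3, byrow = TRUE)   # one value per living state
    } else {
      matrix(rep_len(death_probs, nA), nA, 3)    # one value per age
    }
  }
  if (is.matrix(death_probs) && nrow(death_probs) == 1L) {
    death_probs <- matrix(death_probs, nA, 3, byrow = TRUE)
  }
  stopifnot(is.matrix(death_probs), nrow(death_probs) == nA,
            ncol(death_probs) == 3)
  if (any(death_probs < 0 | death_probs > 1)) {
    stop("replacement death probabilities must lie in [0, 1]")
  }
  P <- table$P
  for (s in 1:3) {
    q_old <- P[, s, 4]
    q_new <- death_probs[, s]
    alive_old <- 1 - q_old
    alive_new <- 1 - q_new
    for (t in 1:3) {
      share <- ifelse(alive_old > 0, P[, s, t] / alive_old,
                      as.numeric(t == s))  # no surviving mass before: stay
      P[, s, t] <- alive_new * share
    }
    P[, s, 4] <- q_new
  }
  transition_table(P, sex = table$sex, ages = table$ages)
}

#' @rdname transition_table
#' @param table a `transition_table`.
#' @return `death_probs()` extracts the `length(ages) x 3` matrix of annual
#'   death probabilities from the living states.
#' @export
death_probs <- function(table) {
  stopifnot(inherits(table, "transition_table"))
  table$P[, 1:3, 4, drop = TRUE]
}

#' Write / read a transition table as a long-format CSV
#'
#' Columns: sex, age, from_state, to_state, probability, n_transitions,
#' n_at_risk.  The reader round-trips what the writer produced.
#'
#' @param table a `transition_table`.
#' @param path file path.
#' @export
write_transitions <- function(table, path) {
  st <- state_levels()
  long <- data.table::as.data.table(
    expand.grid(age = table$ages, from_state = st, to_state = st,
                stringsAsFactors = FALSE)
  )
  long[, "sex" := table$sex]
  data.table::setcolorder(long, c("sex", "age", "from_state", "to_state"))
  idx <- cbind(match(long$age, table$ages),
               match(long$from_state, st), match(long$to_state, st))
  long$probability <- table$P[idx]
  long$n_transitions <- if (!is.null(table$n_trans)) table$n_trans[idx] else NA_integer_
  long$n_at_risk <- if (!is.null(table$n_at_risk)) {
    table$n_at_risk[cbind(idx[, 1], idx[, 2])]
  } else NA_integer_
  data.table::setorder(long, age, from_state, to_state)
  data.table::fwrite(long, path)
  invisible(path)
}

#' @rdname write_transitions
#' @return `read_transitions()` returns a `transition_table`.
#' @export
read_transitions <- function(path) {
  long <- data.table::fread(path)
  ages <- sort(unique(long$age))
  st <- state_levels()
  P <- array(0, dim = c(length(ages), 4, 4))
  ntr <- array(0L, dim = c(length(ages), 4, 4))
  nar <- matrix(0L, length(ages), 4)
  idx <- cbind(match(long$age, ages), match(long$from_state, st),
               match(long$to_state, st))
  P[idx] <- long$probability
  if (!all(is.na(long$n_transitions))) ntr[idx] <- long$n_transitions
  if (!all(is.na(long$n_at_risk))) nar[cbind(idx[, 1], idx[, 2])] <- long$n_at_risk
  transition_table(P, n_trans = ntr, n_at_risk = nar,
                   sex = as.character(long$sex[1]), ages = ages)
}
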