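#' Sullivan life table partitioning life expectancy by diabetes prevalence
#'
#' Standard period life-table recursion combined with age-specific disease
#' prevalence: `l(x+1) = l(x) (1 - q(x))`, `L(x) = l(x) - 0.5 d(x)`
#' (deaths mid-interval), `e(x) = sum_{y >= x} L(y) / l(x)`, and the
#' Sullivan partition `e_with_dm(x) = sum_{y >= x} prev(y) L(y) / l(x)`,
#' `e_without_dm = e - e_with_dm`.  The table is closed at the final age by
#' assuming all survivors die there with half-year exposure
#' (`L(last) = 0.5 l(last)`).
#'
#' @param death_probs numeric vector of annual death probabilities `q(x)`.
#' @param prevalence numeric vector of the fraction of person-years lived
#'   in the diabetes state at each age; missing values at sparse old ages
#'   are forward-filled from the last observed age (zero before the first
#'   observed age).
#' @param ages integer ages the inputs refer to
#'   (default `0:(length(death_probs) - 1)`).
#' @param radix number of survivors at the first age (default 100,000).
#' @return a `data.frame` of class `life_table` with columns `age`, `q`,
#'   `l`, `d`, `L`, `prevalence`, `e`, `e_with_dm`, `e_without_dm`.
#' @export
build_life_table <- function(death_probs, prevalence,
                             ages = seq_along(death_probs) - 1L,
                             radix = 1e5) {
  q <- death_probs
  n <- length(q)
  stopifnot(length(prevalence) == n, length(ages) == n)
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("death probabilities outside [0, 1]")
  if (any(prevalence < 0 | prevalence > 1, na.rm = TRUE)) {
    stop("prevalence outside [0, 1]")
  }
  if (anyNA(q)) stop("death probabilities must be complete")
  prev <- .forward_fill(prevalence)
  l <- radix * cumprod(c(1, 1 - q))[seq_len(n)]
  d <- l * q
  L <- l - 0.5 * d
  # closure: all survivors at the final age die there with half-year exposure
  L[n] <- 0.5 * l[n]
  Tx <- rev(cumsum(rev(L)))
  Twith <- rev(cumsum(rev(prev * L)))
  e <- ifelse(l > 0, Tx / l, 0)
  e_with <- ifelse(l > 0, Twith / l, 0)
  out <- data.frame(age = ages, q = q, l = l, d = d, L = L,
                    prevalence = prev, e = e, e_with_dm = e_with,
                    e_without_dm = e - e_with)
  class(out) <- c("life_table", class(out))
  out
}

.forward_fill <- function(x) {
  if (!anyNA(x)) return(x)
  filled <- x
  last <- 0
  for (i in seq_along(x)) {
    if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
  }
  filled
}

#' Age-specific diabetes prevalence of a simulated cohort
#'
#' Fraction of alive person-years at each age spent in the diabetes state:
#' a person contributes the year at age `a` if alive at `a` (death age
#' greater than `a`, or truncated alive), and counts as diabetic from the
#' onset age onward.  Ages with no alive person-years yield `NA`, which
#' [build_life_table()] forward-fills.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param ages integer ages to evaluate (default the cohort's age range).
#' @return a named numeric vector of prevalences by age.
#' @export
prevalence_from_cohort <- function(cohort, ages = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"), nrow(cohort) > 0)
  if (is.null(ages)) {
    ages <- attr(cohort, "start_age"):attr(cohort, "terminal_age")
  }
  dth <- cohort$death_age
  dm <- cohort$dm_onset
  out <- vapply(ages, function(a) {
    alive <- is.na(dth) | dth > a
    n_alive <- sum(alive)
    if (n_alive == 0) return(NA_real_)
    sum(alive & !is.na(dm) & dm <= a) / n_alive
  }, numeric(1))
  names(out) <- ages
  out
}

#' @rdname prevalence_from_cohort
#' @return `mortality_from_cohort()` returns the annual all-state death
#'   probability `q(a)` of the cohort (deaths during `[a, a+1)` over alive
#'   at `a`); the final age is closed with `q = 1`.
#' @export
mortality_from_cohort <- function(cohort, ages = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"), nrow(cohort) > 0)
  term <- attr(cohort, "terminal_age")
  if (is.null(ages)) ages <- attr(cohort, "start_age"):term
  dth <- cohort$death_age
  out <- vapply(ages, function(a) {
    alive <- is.na(dth) | dth > a
    n_alive <- sum(alive)
    if (n_alive == 0) return(NA_real_)
    sum(!is.na(dth) & dth == a + 1L) / n_alive
  }, numeric(1))
  out[ages == term] <- 1
  out <- .forward_fill(out)
  names(out) <- ages
  out
}

#' Sullivan cross-check of a simulated cohort
#'
#' Convenience wrapper: derives mortality and prevalence from the cohort
#' and builds the Sullivan life table on the cohort's age range.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return a `life_table`.
#' @export
sullivan_from_cohort <- function(cohort) {
  ages <- attr(cohort, "start_age"):attr(cohort, "terminal_age")
  build_life_table(mortality_from_cohort(cohort, ages),
                   prevalence_from_cohort(cohort, ages),
                   ages = ages, radix = 1e5)
}
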