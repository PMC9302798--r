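#' Age-period-cohort rate model with natural cubic splines
#'
#' Poisson log-linear model for event rates on age x period cells with an
#' exposure offset and natural cubic spline effects of age, period and
#' birth cohort (`cohort = period - age`).  The exact linear collinearity
#' of the three timescales is resolved by constraining the period effect to
#' curvature only (zero slope): each period basis column is residualised on
#' a linear function of period, so any linear drift is carried by the age
#' and cohort effects, whose slopes are then identified.  This matches the
#' model's purpose of predicting cohort-indexed rates at ages without data;
#' users who prefer drift on the period axis can refit after swapping the
#' roles of the dimensions.
#'
#' Interior knots default to three per dimension, evenly spaced within the
#' observed range; boundary knots sit at the extremes, beyond which the
#' natural spline extrapolates linearly.  A custom knot list
#' (`list(age = ..., period = ..., cohort = ...)`) reproduces the
#' inspect-the-plot workflow of placing knots at inflection points.
#'
#' @param cells `data.frame` with columns `age`, `period`, `events`,
#'   `person_years`; cells with zero exposure are dropped.
#' @param knots optional named list of interior knot positions per
#'   dimension.
#' @param outcome label stored with the model (e.g.
#'   `"dm_incidence_from_pre"`, `"mortality"`).
#' @return an object of class `apc_model`.
#' @export
fit_apc <- function(cells, knots = NULL, outcome = "rate") {
  cells <- as.data.frame(cells)
  need <- c("age", "period", "events", "person_years")
  if (!all(need %in% names(cells))) {
    stop("cells must have columns: ", paste(need, collapse = ", "))
  }
  cells <- cells[cells$person_years > 0, ]
  if (nrow(cells) == 0) stop("no cells with positive exposure")
  cells$cohort <- cells$period - cells$age

  default_knots <- function(x) {
    r <- range(x)
    if (diff(r) <= 0) return(numeric(0))
    seq(r[1], r[2], length.out = 5)[2:4]
  }
  kn <- list(
    age = if (!is.null(knots$age)) knots$age else default_knots(cells$age),
    period = if (!is.null(knots$period)) knots$period else default_knots(cells$period),
    cohort = if (!is.null(knots$cohort)) knots$cohort else default_knots(cells$cohort)
  )
  for (d in names(kn)) {
    r <- range(cells[[d]])
    if (length(kn[[d]]) && any(kn[[d]] < r[1] | kn[[d]] > r[2])) {
      stop("knots outside data range for dimension: ", d)
    }
  }
  basis <- function(x, k) {
    if (length(unique(x)) < 3) return(NULL)
    splines::ns(x, knots = k, Boundary.knots = range(x))
  }
  A <- basis(cells$age, kn$age)
  C <- basis(cells$cohort, kn$cohort)
  Praw <- basis(cells$period, kn$period)
  detrend_fit <- NULL
  Pd <- NULL
  if (!is.null(Praw)) {
    # remove constant + linear component of each period basis column
    detrend_fit <- apply(Praw, 2, function(col) {
      stats::coef(stats::lm(col ~ cells$period))
    })
    Pd <- Praw - cbind(1, cells$period) %*% detrend_fit
    colnames(Pd) <- colnames(Praw)
  }
  X <- cbind(`(Intercept)` = 1,
             if (!is.null(A)) structure(A, dimnames = list(NULL, paste0("age", seq_len(ncol(A))))),
             if (!is.null(C)) structure(C, dimnames = list(NULL, paste0("coh", seq_len(ncol(C))))),
             if (!is.null(Pd)) structure(Pd, dimnames = list(NULL, paste0("per", seq_len(ncol(Pd))))))
  fit <- stats::glm.fit(X, cells$events,
                        offset = log(cells$person_years),
                        family = stats::poisson())
  beta <- fit$coefficients
  if (all(is.na(beta))) stop("rank deficiency: no estimable effects")
  beta[is.na(beta)] <- 0
  structure(
    list(outcome = outcome, coefficients = beta,
         age_basis = A, cohort_basis = C, period_basis = Praw,
         period_detrend = detrend_fit,
         knots = kn, data_range = list(age = range(cells$age),
                                       period = range(cells$period),
                                       cohort = range(cells$cohort)),
         fitted_rates = fit$fitted.values / cells$person_years,
         cells = cells, deviance = fit$deviance),
    class = "apc_model"
  )
}

#' @export
print.apc_model <- function(x, ...) {
  cat(sprintf("Age-period-cohort spline rate model (%s)\n", x$outcome))
  cat(sprintf("  fitted on %d cells; age %g-%g, period %g-%g, cohort %g-%g\n",
              nrow(x$cells), x$data_range$age[1], x$data_range$age[2],
              x$data_range$period[1], x$data_range$period[2],
              x$data_range$cohort[1], x$data_range$cohort[2]))
  cat(sprintf("  residual deviance: %.1f\n", x$deviance))
  invisible(x)
}

#' Predicted rates of an age-period-cohort model
#'
#' Evaluates the fitted log-linear rate at arbitrary (age, cohort) points
#' (`period = cohort + age`); natural-spline effects extrapolate linearly
#' outside the observed range of each timescale.
#'
#' @param object an [fit_apc()] model.
#' @param age,cohort numeric vectors (recycled to common length).
#' @param ... unused.
#' @return numeric vector of predicted rates (events per person-year).
#' @export
predict.apc_model <- function(object, age, cohort, ...) {
  n <- max(length(age), length(cohort))
  age <- rep_len(age, n); cohort <- rep_len(cohort, n)
  period <- cohort + age
  cols <- list(`(Intercept)` = rep(1, n))
  expand <- function(b, x, prefix) {
    if (is.null(b)) return(NULL)
    m <- stats::predict(b, x)
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
    m
  }
  A <- expand(object$age_basis, age, "age")
  C <- expand(object$cohort_basis, cohort, "coh")
  Pm <- NULL
  if (!is.null(object$period_basis)) {
    Pr <- stats::predict(object$period_basis, period)
    Pm <- Pr - cbind(1, period) %*% object$period_detrend
    colnames(Pm) <- paste0("per", seq_len(ncol(Pm)))
  }
  X <- cbind(rep(1, n), A, C, Pm)
  colnames(X)[1] <- "(Intercept)"
  beta <- object$coefficients[colnames(X)]
  as.numeric(exp(X %*% beta))
}

#' Predicted rate surface on an (age, cohort) grid
#'
#' @param model an [fit_apc()] model.
#' @param ages,cohorts grid axes (defaults: ages 0-110, cohorts 1900-1980).
#' @return a `data.frame` with `cohort`, `age`, `rate`.
#' @export
apc_rate_grid <- function(model, ages = 0:110, cohorts = 1900:1980) {
  g <- expand.grid(age = ages, cohort = cohorts)
  g$rate <- predict(model, g$age, g$cohort)
  g[c("cohort", "age", "rate")]
}

#' Birth-cohort lifetime risk from extrapolated rates
#'
#' Converts extrapolated annual incidence and mortality rates of a birth
#' cohort into annual probabilities via `p = 1 - exp(-rate)` (which keeps
#' probabilities in `[0, 1]` for any rate) and accumulates them with the
#' modified Kaplan-Meier sum, treating death as a competing event.
#'
#' @param incidence_model [fit_apc()] model of diabetes incidence from the
#'   origin state of interest.
#' @param mortality_model [fit_apc()] model of mortality, or `NULL` for no
#'   competing mortality.
#' @param birth_year birth cohort.
#' @param index_age first age at risk.
#' @param max_age terminal age (default 110).
#' @return the lifetime risk (scalar probability).
#' @export
cohort_lifetime_risk <- function(incidence_model, mortality_model = NULL,
                                 birth_year, index_age, max_age = 110L) {
  ages <- index_age:(max_age - 1L)
  r_inc <- predict(incidence_model, ages, rep(birth_year, length(ages)))
  if (any(!is.finite(r_inc))) {
    stop("incidence model grid gap at ages: ",
         paste(ages[!is.finite(r_inc)], collapse = ", "))
  }
  p_inc <- 1 - exp(-r_inc)
  p_dth <- if (is.null(mortality_model)) {
    rep(0, length(ages))
  } else {
    r_d <- predict(mortality_model, ages, rep(birth_year, length(ages)))
    if (any(!is.finite(r_d))) {
      stop("mortality model grid gap at ages: ",
           paste(ages[!is.finite(r_d)], collapse = ", "))
    }
    1 - exp(-r_d)
  }
  mkm_from_probs(p_inc, p_dth)
}

#' Events/exposure cells for APC fitting from resolved histories
#'
#' Tabulates observed transitions into diabetes (from a chosen origin
#' state) or deaths, and the corresponding person-years, by integer age and
#' calendar period, using the same observation windows as
#' [estimate_transitions()].
#'
#' @param histories resolved histories (with `birth_year`).
#' @param outcome `"dm_incidence_from_pre"`, `"dm_incidence_from_normo"`
#'   or `"mortality"`.
#' @return a `data.frame` with `age`, `period`, `events`, `person_years`.
#' @export
apc_cells <- function(histories,
                      outcome = c("dm_incidence_from_pre",
                                  "dm_incidence_from_normo", "mortality")) {
  outcome <- match.arg(outcome)
  h <- data.table::as.data.table(histories)
  if (all(is.na(h$birth_year))) stop("histories carry no birth years")
  rows <- .person_age_rows(h, 110L)
  if (outcome == "mortality") {
    tab <- rows$vital
    tab[, period := h$birth_year[person] + age]
    ev <- tab[, list(events = sum(dead), person_years = .N),
              by = list(age, period)]
  } else {
    from_sel <- if (outcome == "dm_incidence_from_pre") 2L else 1L
    tab <- rows$glyc[from == from_sel]
    tab[, period := h$birth_year[person] + age]
    ev <- tab[, list(events = sum(to == 3L), person_years = .N),
              by = list(age, period)]
  }
  data.table::setorder(ev, period, age)
  as.data.frame(ev)
}
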