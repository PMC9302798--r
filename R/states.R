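#' Glycemic states
#'
#' The analysis works on a four-state illness-death model with the mutually
#' exclusive states normoglycemia (`"NORMO"`), prediabetes (`"PRE"`),
#' diabetes (`"DM"`) and death (`"DEATH"`). Severity is ordered
#' NORMO < PRE < DM; DM is absorbing among the living states and DEATH is
#' absorbing overall.
#'
#' @return `state_levels()` returns the four state labels in severity order.
#' @export
state_levels <- function() c("NORMO", "PRE", "DM", "DEATH")

# integer codes used internally: 1=NORMO, 2=PRE, 3=DM, 4=DEATH
.STATE_N <- 1L
.STATE_P <- 2L
.STATE_D <- 3L
.STATE_X <- 4L

#' @rdname state_levels
#' @param x character vector of state labels.
#' @return `state_index()` returns the integer severity code (1-4) of each
#'   label, erroring on unknown labels.
#' @export
state_index <- function(x) {
  i <- match(x, state_levels())
  if (anyNA(i)) {
    stop("unknown state label(s): ", paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i
}

# ADA diagnostic bands.  Values at or above `pre` and below `dm` classify as
# prediabetes; values at or above `dm` classify as diabetes.  Units:
# FPG and 2h-OGTT in mmol/L, HbA1c in mmol/mol.
.GLYCEMIC_BANDS <- list(
  FPG    = c(pre = 5.6, dm = 7.0),
  HbA1c  = c(pre = 39,  dm = 48),
  OGTT2h = c(pre = 7.8, dm = 11.1)
)

.MEASUREMENT_KINDS <- c("FPG", "HbA1c", "OGTT2h", "RPG")
.RECORD_KINDS <- c(.MEASUREMENT_KINDS,
                   "dx_code", "noninsulin_drug", "insulin_episode", "death")

#' Classify a single glycemic measurement
#'
#' Maps a measurement to NORMO/PRE/DM according to the American Diabetes
#' Association thresholds: FPG >= 5.6 and < 7.0 mmol/L, HbA1c >= 39 and
#' < 48 mmol/mol, or 2-hour OGTT >= 7.8 and < 11.1 mmol/L classify as
#' prediabetes; values at or above the upper bound classify as diabetes;
#' values below the lower bound as normoglycemia.  Random plasma glucose
#' (`"RPG"`) is ingested but never yields PRE or DM on its own.
#'
#' @param kind character vector of measurement kinds
#'   (`"FPG"`, `"HbA1c"`, `"OGTT2h"`, `"RPG"`).
#' @param value numeric vector of measurement values (mmol/L for glucose,
#'   mmol/mol for HbA1c).
#' @return character vector of state labels (`"NORMO"`, `"PRE"` or `"DM"`).
#' @examples
#' classify_measurement("FPG", 6.0)     # "PRE"
#' classify_measurement("HbA1c", 48)    # "DM"
#' classify_measurement("OGTT2h", 7.7)  # "NORMO"
#' @export
classify_measurement <- function(kind, value) {
  kind <- as.character(kind)
  bad <- !kind %in% .MEASUREMENT_KINDS
  if (any(bad)) {
    stop("unknown measurement kind(s): ", paste(unique(kind[bad]), collapse = ", "))
  }
  if (!is.numeric(value)) stop("measurement values must be numeric")
  n <- max(length(kind), length(value))
  kind <- rep_len(kind, n)
  value <- rep_len(value, n)
  if (any(!is.na(value) & value < 0)) stop("measurement values must be non-negative")
  if (anyNA(value)) stop("measurement values must not be missing")
  out <- rep("NORMO", n)
  for (k in names(.GLYCEMIC_BANDS)) {
    b <- .GLYCEMIC_BANDS[[k]]
    sel <- kind == k
    out[sel & value >= b["pre"]] <- "PRE"
    out[sel & value >= b["dm"]] <- "DM"
  }
  out
}

#' @rdname classify_measurement
#' @return `glycemic_bands()` returns the list of (pre, dm) thresholds per
#'   measurement kind.
#' @export
glycemic_bands <- function() .GLYCEMIC_BANDS
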