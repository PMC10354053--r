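#' Classify an EDSS transition
#'
#' A transition is "worsening" when EDSS increases by at least 1.0 point,
#' "improved" when it decreases by at least 1.0 point, and "stable"
#' otherwise. Both scores must lie on the 0.5-step EDSS grid (0, 0.5, ..., 10).
#'
#' @param prev_edss,cur_edss EDSS at the previous and current visit.
#' @return Character vector with levels "worsening", "improved", "stable".
#' @examples
#' classify_transition(2.0, 3.0) # worsening
#' classify_transition(3.0, 3.5) # stable
#' @export
classify_transition <- function(prev_edss, cur_edss) {
  check_edss_grid(prev_edss)
  check_edss_grid(cur_edss)
  diff <- cur_edss - prev_edss
  ifelse(diff >= 1.0, "worsening", ifelse(diff <= -1.0, "improved", "stable"))
}

check_edss_grid <- function(x, what = "EDSS") {
  bad <- is.finite(x) & (x < 0 | x > 10 | abs(x * 2 - round(x * 2)) > 1e-8)
  if (any(bad))
    stop(what, " values must lie on the 0.5-point grid in [0, 10]; offending: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  invisible(x)
}

# covariate columns carried from the start-visit onto each interval
.covariate_cols <- c("sex", "age_at_onset", "bmi", "t2l_count", "vitd_status",
                     "site", "latitude", "dmt_category", "dur_dmt1", "dur_dmt3",
                     "relapse_count")

#' Build counting-process transition intervals from visit records
#'
#' Converts a long-format visit table (one row per clinical assessment) into
#' half-open counting-process intervals `(start, stop]`, one per consecutive
#' visit pair, with the worsening/improved/stable status determined by the
#' EDSS change over the interval. Visits with missing EDSS are dropped before
#' pairing; subjects with a single (remaining) visit contribute no interval.
#' Covariates are carried from the start visit (so time-varying covariates
#' such as cumulative DMT duration are left-continuous step functions), and a
#' running count of previously confirmed-or-reported relapses is exposed as
#' `relapse_count`.
#'
#' @param visits Data frame with at least `subject_id`, `time`, `edss`;
#'   optionally `relapse_flag` and the covariate columns
#'   (`sex`, `age_at_onset`, `bmi`, `t2l_count`, `vitd_status`, `latitude`,
#'   `dmt_category`, `dmt_duration`).
#' @return Data frame of class `transition_intervals` with columns
#'   `subject_id`, `start`, `stop`, `status`, `event` (1 for worsening),
#'   `relapse_reported`, `relapse_event` (initialized to the reported flag
#'   at stop; see [confirm_relapses()]), `prev_edss`, `cur_edss`, and any
#'   covariates present.
#' @examples
#' v <- data.frame(subject_id = 1, time = 0:4,
#'                 edss = c(2, 3, 3, 2, 3.5))
#' build_transitions(v)$status
#' @export
build_transitions <- function(visits) {
  stopifnot(is.data.frame(visits))
  req <- c("subject_id", "time", "edss")
  miss <- setdiff(req, names(visits))
  if (length(miss)) stop("visits lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(visits$time < 0, na.rm = TRUE))
    stop("visit times must be non-negative", call. = FALSE)
  visits <- visits[order(visits$subject_id, visits$time), , drop = FALSE]
  dup <- stats::ave(visits$time, visits$subject_id,
                    FUN = function(t) c(0, as.numeric(diff(t) == 0)))
  if (any(dup == 1))
    stop("duplicate visit times within subject", call. = FALSE)
  if (!"relapse_flag" %in% names(visits)) visits$relapse_flag <- FALSE
  # listwise deletion of missing-EDSS visits before pairing
  visits <- visits[!is.na(visits$edss), , drop = FALSE]
  if (nrow(visits) == 0L) return(.empty_transitions())
  check_edss_grid(visits$edss)

  sid <- visits$subject_id
  n <- nrow(visits)
  same <- c(sid[-n] == sid[-1L], FALSE)   # row i starts an interval ending at i+1
  i0 <- which(same)
  if (!length(i0)) return(.empty_transitions())
  i1 <- i0 + 1L

  out <- data.frame(
    subject_id = sid[i0],
    start = visits$time[i0],
    stop = visits$time[i1],
    prev_edss = visits$edss[i0],
    cur_edss = visits$edss[i1],
    relapse_reported = as.logical(visits$relapse_flag[i1]),
    stringsAsFactors = FALSE
  )
  out$status <- classify_transition(out$prev_edss, out$cur_edss)
  out$event <- as.integer(out$status == "worsening")
  out$relapse_event <- out$relapse_reported
  # running count of relapses reported strictly before the interval start
  rc <- stats::ave(as.numeric(visits$relapse_flag), sid,
                   FUN = function(x) cumsum(x))
  out$relapse_count <- rc[i0]
  for (cc in setdiff(.covariate_cols, "relapse_count"))
    if (cc %in% names(visits)) out[[cc]] <- visits[[cc]][i0]
  rownames(out) <- NULL
  class(out) <- c("transition_intervals", "data.frame")
  out
}

.empty_transitions <- function() {
  out <- data.frame(subject_id = character(0), start = numeric(0),
                    stop = numeric(0), prev_edss = numeric(0),
                    cur_edss = numeric(0), relapse_reported = logical(0),
                    status = character(0), event = integer(0),
                    relapse_event = logical(0), relapse_count = numeric(0))
  class(out) <- c("transition_intervals", "data.frame")
  out
}

#' Confirm reported relapses against the EDSS change
#'
#' A reported relapse is confirmed only when the stop-visit of its interval
#' shows a clinically meaningful EDSS change (at least 1 point in absolute
#' value). All other reported relapses are excluded. The operation is
#' idempotent and never adds events beyond the reported flags.
#'
#' @param visits The visit table the transitions were built from (unused
#'   beyond validation; the reported flags already live on the intervals).
#' @param transitions A `transition_intervals` data frame.
#' @return The transitions with `relapse_event` replaced by the confirmed
#'   indicator.
#' @export
confirm_relapses <- function(visits, transitions) {
  stopifnot(inherits(transitions, "transition_intervals"))
  meaningful <- abs(transitions$cur_edss - transitions$prev_edss) >= 1.0
  transitions$relapse_event <- transitions$relapse_reported & meaningful
  transitions
}

#' Lag survival times
#'
#' Shifts every interval stop time back by `lag` months so that the hazard
#' at the original event time reads the longitudinal marker `lag` earlier
#' (the PIRA-style sensitivity analysis). Intervals whose shifted stop falls
#' at or before their start are dropped. `lag = 0` is the identity.
#'
#' @param transitions A `transition_intervals` data frame.
#' @param lag Lag in months (non-negative; the analysis uses 0, 3 or 6).
#' @return Lagged transitions.
#' @export
lag_survival_times <- function(transitions, lag) {
  stopifnot(inherits(transitions, "transition_intervals"))
  if (length(lag) != 1L || !is.finite(lag) || lag < 0)
    stop("lag must be a single non-negative number of months", call. = FALSE)
  if (lag == 0) return(transitions)
  transitions$stop <- transitions$stop - lag / 12
  keep <- transitions$stop > transitions$start
  out <- transitions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a visit table from CSV
#'
#' @param path Path to a CSV with one row per visit.
#' @return Data frame of visits sorted by subject and time.
#' @export
read_visits <- function(path) {
  v <- utils::read.csv(path, stringsAsFactors = FALSE)
  v[order(v$subject_id, v$time), , drop = FALSE]
}

#' Write transition intervals to CSV
#'
#' @param transitions A `transition_intervals` data frame.
#' @param path Output path.
#' @export
write_transitions <- function(transitions, path) {
  utils::write.csv(as.data.frame(transitions), path, row.names = FALSE)
  invisible(path)
}
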