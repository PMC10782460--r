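#' Build the risk-set index for an event table
#'
#' Every estimator in the package consumes this index rather than the raw
#' table. It maps each interval row to the integer days on which the subject
#' is at risk, records which rows carry events and on which days, and stores
#' the event-day grid `t_1 < ... < t_M` (the unique days with at least one
#' event) together with per-day event totals. Because a subject enters at the
#' beginning of a day and exits at the end of a day, the at-risk days of a
#' subject's first interval `(start, stop]` are `start..stop` (the entry day
#' counts) and those of any later interval are `start+1..stop`.
#'
#' @param table a validated [event_table()].
#' @param tau end of the study window (integer day); defaults to the latest
#'   `stop` in the table. Events after `tau` are an error.
#' @return an object of class `"risk_index"`: a list with the day window
#'   `tau`, counts `n`, `n_facility`, `p`, label lookups, per-row arrays
#'   (`lo`, `hi`, `fac`, `subj`, `eday`, covariate matrix `Z`) sorted by
#'   facility, and the event grid (`event_times`, `dN_total`).
#' @export
risk_index <- function(table, tau = NULL) {
  if (!inherits(table, "event_table"))
    table <- event_table(as.data.frame(table),
                         covariates = attr(table, "covariates"))
  covariates <- attr(table, "covariates")
  if (is.null(tau)) tau <- max(table$stop)
  tau <- as.integer(tau)
  if (tau < max(table$stop))
    stop("tau is smaller than the latest stop day")
  if (sum(table$event) == 0L)
    stop("no events anywhere: the baseline rate is not estimable")

  subj_levels <- unique(table$subject_id)
  fac_levels <- sort(unique(table$facility_id))
  subj <- match(table$subject_id, subj_levels)
  fac <- match(table$facility_id, fac_levels)

  # first interval per subject starts at the entry day B_i
  entry <- tapply(table$start, subj, min)[as.character(subj)]
  first <- table$start == as.integer(entry)
  lo <- ifelse(first, table$start, table$start + 1L)
  hi <- table$stop
  eday <- ifelse(table$event == 1L, table$stop, -1L)

  ord <- order(fac, subj, lo)
  Z <- as.matrix(as.data.frame(table)[, covariates, drop = FALSE])
  storage.mode(Z) <- "double"

  ev_days <- hi[table$event == 1L]
  event_times <- sort(unique(ev_days))
  dN_total <- as.integer(table(factor(ev_days, levels = event_times)))

  structure(list(
    tau = tau,
    n = length(subj_levels),
    n_facility = length(fac_levels),
    p = length(covariates),
    subject_levels = subj_levels,
    facility_levels = fac_levels,
    covariates = covariates,
    lo = as.integer(lo[ord]), hi = as.integer(hi[ord]),
    fac = as.integer(fac[ord]), subj = as.integer(subj[ord]),
    eday = as.integer(eday[ord]),
    Z = Z[ord, , drop = FALSE],
    event_times = as.integer(event_times),
    dN_total = dN_total
  ), class = "risk_index")
}

#' @export
print.risk_index <- function(x, ...) {
  cat(sprintf(
    "risk_index: %d subjects in %d facilities, %d covariates, %d event days (window [0, %d])\n",
    x$n, x$n_facility, x$p, length(x$event_times), x$tau))
  invisible(x)
}

# at-risk indicator matrix helpers used by the plain-R implementations -------

# sum over at-risk days of per-day values `day_values` (length tau+1, day 0
# first) for each row of the index, as a vector over rows
.row_range_sums <- function(index, day_values) {
  cum <- c(0, cumsum(day_values))
  cum[index$hi + 2L] - cum[index$lo + 1L]
}

# per-day totals sum_i Y_i(t) * wt_i(row) over all rows, days 0..tau
.day_totals <- function(index, wt) {
  d <- numeric(index$tau + 2L)
  agg_lo <- rowsum(wt, index$lo)
  agg_hi <- rowsum(wt, index$hi + 1L)
  d[as.integer(rownames(agg_lo)) + 1L] <- agg_lo[, 1L]
  d[as.integer(rownames(agg_hi)) + 1L] <-
    d[as.integer(rownames(agg_hi)) + 1L] - agg_hi[, 1L]
  cumsum(d)[seq_len(index$tau + 1L)]
}
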