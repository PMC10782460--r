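#' Counting-process event-history tables
#'
#' An event table holds clustered recurrent-event histories in long
#' counting-process format on an integer-day calendar grid: one row per
#' at-risk interval `(start, stop]` with an event indicator at `stop` and the
#' covariate values that apply on that interval. Entrances happen at the
#' beginning of a day and events and exits at the end of a day (events
#' preceding exits), so a subject is at risk for an event on both the entry
#' day and the exit day. Covariates are left-continuous step functions: the
#' value on an interval applies to every day in it.
#'
#' @param data a data.frame with columns `subject_id`, `facility_id`,
#'   `start`, `stop`, `event`, plus one numeric column per covariate.
#' @param covariates character vector naming the covariate columns; defaults
#'   to every column other than the five reserved ones.
#' @return the validated table, classed `"event_table"`, with attributes
#'   `covariates` (column names) and the rows sorted by subject and start.
#'
#' @details Validation enforces, per subject: integer `start < stop`,
#'   non-overlapping intervals, at most one event per subject-day, a single
#'   facility, and no missing covariate values. Gaps between a subject's
#'   intervals are allowed (the subject is simply not at risk there).
#' @export
event_table <- function(data, covariates = NULL) {
  reserved <- c("subject_id", "facility_id", "start", "stop", "event")
  missing_cols <- setdiff(reserved, names(data))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(data), reserved)
  bad <- setdiff(covariates, names(data))
  if (length(bad))
    stop("unknown covariate columns: ", paste(bad, collapse = ", "))

  data <- as.data.frame(data)[, c(reserved, covariates)]
  data$subject_id <- as.character(data$subject_id)
  data$facility_id <- as.character(data$facility_id)

  if (nrow(data) == 0L) stop("empty table")
  for (col in c("start", "stop")) {
    v <- data[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v != floor(v)))
      stop("column '", col, "' must hold non-negative integer days")
    data[[col]] <- as.integer(v)
  }
  if (any(data$start < 0L)) stop("negative start day")
  if (!all(data$event %in% c(0, 1)))
    stop("event must be 0 or 1 (at most one event per subject-day)")
  data$event <- as.integer(data$event)
  for (cv in covariates) {
    if (!is.numeric(data[[cv]]))
      stop("covariate '", cv, "' is not numeric")
    if (anyNA(data[[cv]]))
      stop("missing values in covariate '", cv, "' (no imputation is done)")
  }

  bad_len <- data$subject_id[data$start >= data$stop]
  if (length(bad_len))
    stop("start >= stop for subject ", bad_len[1L])

  ord <- order(data$subject_id, data$start)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  sid <- data$subject_id
  new_subj <- c(TRUE, sid[-1L] != sid[-length(sid)])
  # overlap: within a subject, each interval must start at or after the
  # previous stop
  prev_stop <- c(NA_integer_, data$stop[-nrow(data)])
  overl <- !new_subj & data$start < prev_stop
  if (any(overl))
    stop("overlapping intervals for subject ", sid[which(overl)[1L]])

  fac_per_subj <- tapply(data$facility_id, sid, function(x) length(unique(x)))
  if (any(fac_per_subj > 1L))
    stop("facility changes within subject ",
         names(fac_per_subj)[which(fac_per_subj > 1L)[1L]])

  ev <- data[data$event == 1L, c("subject_id", "stop")]
  if (nrow(ev) && anyDuplicated(ev))
    stop("more than one event on the same day for subject ",
         ev$subject_id[which(duplicated(ev))[1L]])

  attr(data, "covariates") <- covariates
  class(data) <- c("event_table", "data.frame")
  data
}

#' Validate an existing event table
#'
#' Re-runs all [event_table()] invariant checks; useful after manual edits.
#' @param table an object coercible to an event table.
#' @return the validated `event_table`.
#' @export
validate_event_table <- function(table) {
  event_table(as.data.frame(table), covariates = attr(table, "covariates"))
}

#' Read / write event tables as CSV
#'
#' The CSV dialect is a UTF-8 header
#' `subject_id,facility_id,start,stop,event,<covariate names...>`. Doubles are
#' written with full round-trip precision, so write-then-read preserves every
#' field exactly.
#'
#' @param path file path.
#' @rdname event_table_io
#' @return `read_event_table` returns a validated [event_table()];
#'   `write_event_table` returns `path` invisibly.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, data.table = FALSE, colClasses = list(
    character = c("subject_id", "facility_id")))
  reserved <- c("subject_id", "facility_id", "start", "stop", "event")
  for (cv in setdiff(names(df), reserved)) df[[cv]] <- as.double(df[[cv]])
  event_table(df)
}

#' @param table an [event_table()].
#' @rdname event_table_io
#' @export
write_event_table <- function(table, path) {
  df <- as.data.frame(table)
  # 17 significant digits round-trip every double exactly
  for (cn in names(df))
    if (is.double(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' @export
print.event_table <- function(x, ...) {
  cv <- attr(x, "covariates")
  cat(sprintf(
    "event_table: %d rows, %d subjects, %d facilities, %d events, %d covariate%s\n",
    nrow(x), length(unique(x$subject_id)), length(unique(x$facility_id)),
    sum(x$event), length(cv), if (length(cv) == 1L) "" else "s"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
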