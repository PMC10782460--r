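#' Build the time-varying COVID-19 stage timeline for one patient
#'
#' Constructs the staged post-diagnosis states used as time-varying
#' covariates when modelling hospitalisations in a pandemic year. A patient
#' starts in `no-COVID`. The first COVID-19 diagnosis (day `d1`) opens the
#' COVID state, split into `COVID1` (the first 10 days, `d1..d1+9`,
#' diagnosis day included) and `COVID2`; the COVID state persists until 21
#' consecutive days pass with no further diagnosis, each new diagnosis
#' within the state restarting that clock (the clock starts the day after
#' the most recent diagnosis, so with a last diagnosis on day `d` the state
#' runs through day `d+20` and `post-COVID` begins on day `d+21`). While
#' `post-COVID`, an ordinary diagnosis changes nothing, but a
#' hospitalisation carrying a COVID-19 diagnosis moves the patient to
#' `late-COVID` for the rest of follow-up (absorbing). Stage changes happen
#' at the beginning of a day, preceding any admission on the same day.
#'
#' @param diagnosis_days sorted integer days with a reported COVID-19
#'   diagnosis (any source). Days outside the follow-up window are dropped
#'   with a warning.
#' @param covid_hosp_days sorted integer days of hospital admissions coded
#'   with a COVID-19 diagnosis (a subset of diagnosis events; days listed
#'   here need not be repeated in `diagnosis_days`).
#' @param followup integer vector `c(first_day, last_day)` (inclusive).
#' @return data.frame of class `"stage_timeline"`: columns `start_day`,
#'   `end_day` (inclusive) and `stage`, partitioning the follow-up.
#' @examples
#' covid_stages(100L, followup = c(0L, 200L))
#' @export
covid_stages <- function(diagnosis_days = integer(0),
                         covid_hosp_days = integer(0),
                         followup) {
  stopifnot(length(followup) == 2L, followup[1L] <= followup[2L])
  f0 <- as.integer(followup[1L]); f1 <- as.integer(followup[2L])
  diagnosis_days <- as.integer(diagnosis_days)
  covid_hosp_days <- as.integer(covid_hosp_days)
  drop_d <- diagnosis_days < f0 | diagnosis_days > f1
  drop_h <- covid_hosp_days < f0 | covid_hosp_days > f1
  if (any(drop_d) || any(drop_h))
    warning("diagnosis days outside the follow-up window were ignored")
  diagnosis_days <- diagnosis_days[!drop_d]
  covid_hosp_days <- covid_hosp_days[!drop_h]
  # a COVID-coded hospitalisation is itself a diagnosis event
  diag_all <- sort(unique(c(diagnosis_days, covid_hosp_days)))

  seg <- function(start, end, stage) {
    if (start > end) return(NULL)
    data.frame(start_day = start, end_day = end, stage = stage)
  }
  pieces <- list()
  if (!length(diag_all)) {
    pieces <- list(seg(f0, f1, "no-COVID"))
  } else {
    d1 <- diag_all[1L]
    # COVID state end: last diagnosis within the state + 20 days
    end <- d1 + 20L
    for (d in diag_all[-1L]) {
      if (d <= end) end <- d + 20L else break
    }
    covid_end <- min(end, f1)
    pieces <- c(pieces, list(
      seg(f0, d1 - 1L, "no-COVID"),
      seg(d1, min(d1 + 9L, covid_end), "COVID1"),
      seg(d1 + 10L, covid_end, "COVID2")))
    if (end < f1) {
      late <- covid_hosp_days[covid_hosp_days > end]
      if (length(late)) {
        h <- late[1L]
        pieces <- c(pieces, list(seg(end + 1L, h - 1L, "post-COVID"),
                                 seg(h, f1, "late-COVID")))
      } else {
        pieces <- c(pieces, list(seg(end + 1L, f1, "post-COVID")))
      }
    }
  }
  out <- do.call(rbind, Filter(Negate(is.null), pieces))
  rownames(out) <- NULL
  class(out) <- c("stage_timeline", "data.frame")
  out
}

#' Stage timelines for many patients
#'
#' Applies [covid_stages()] per patient and stacks the results in a long
#' table suitable for joining back into an [event_table()] as time-varying
#' covariate intervals.
#'
#' @param patients data.frame with columns `subject_id`, `follow_start`,
#'   `follow_end`.
#' @param diagnoses data.frame with columns `subject_id`, `day` (and
#'   optionally logical `covid_hosp` marking COVID-coded admissions).
#' @return data.frame with `subject_id`, `start_day`, `end_day`, `stage`.
#' @export
covid_stage_table <- function(patients, diagnoses) {
  stopifnot(all(c("subject_id", "follow_start", "follow_end") %in%
                  names(patients)),
            all(c("subject_id", "day") %in% names(diagnoses)))
  if (is.null(diagnoses$covid_hosp)) diagnoses$covid_hosp <- FALSE
  out <- lapply(seq_len(nrow(patients)), function(i) {
    sid <- patients$subject_id[i]
    d <- diagnoses[diagnoses$subject_id == sid, , drop = FALSE]
    tl <- covid_stages(d$day[!d$covid_hosp], d$day[d$covid_hosp],
                       c(patients$follow_start[i], patients$follow_end[i]))
    cbind(subject_id = sid, as.data.frame(tl))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
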