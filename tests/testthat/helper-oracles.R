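# Brute-force oracles, deliberately naive (O(n * tau) day scans with
# explicit loops), kept independent of the package's sweep-based internals.

# at-risk day range per interval row: the first interval of a subject covers
# its start day (entry at the beginning of a day), later intervals are
# (start, stop]
oracle_row_days <- function(df) {
  entry <- ave(df$start, df$subject_id, FUN = min)
  data.frame(lo = ifelse(df$start == entry, df$start, df$start + 1L),
             hi = df$stop)
}

# row indices at risk on a given day
oracle_at_risk <- function(df, day, rd = oracle_row_days(df)) {
  which(rd$lo <= day & day <= rd$hi)
}

# stratified Breslow log partial likelihood, summed facility by facility and
# day by day
oracle_loglik <- function(df, covs, beta, tau) {
  Z <- as.matrix(df[, covs, drop = FALSE])
  eta <- drop(Z %*% beta)
  rd <- oracle_row_days(df)
  ll <- 0
  for (j in unique(df$facility_id)) {
    rows_j <- which(df$facility_id == j)
    for (t in 0:tau) {
      ev <- rows_j[df$event[rows_j] == 1L & df$stop[rows_j] == t]
      if (!length(ev)) next
      risk <- intersect(oracle_at_risk(df, t, rd), rows_j)
      ll <- ll + sum(eta[ev]) - length(ev) * log(sum(exp(eta[risk])))
    }
  }
  ll
}

# central-difference score of the oracle log likelihood
oracle_score_fd <- function(df, covs, beta, tau, h = 1e-5) {
  vapply(seq_along(beta), function(k) {
    up <- dn <- beta
    up[k] <- up[k] + h
    dn[k] <- dn[k] - h
    (oracle_loglik(df, covs, up, tau) - oracle_loglik(df, covs, dn, tau)) /
      (2 * h)
  }, numeric(1L))
}

# per-subject score contributions (sandwich building blocks), double loop
oracle_subject_scores <- function(df, covs, beta, tau) {
  Z <- as.matrix(df[, covs, drop = FALSE])
  eta <- drop(Z %*% beta)
  w <- exp(eta)
  rd <- oracle_row_days(df)
  subs <- unique(df$subject_id)
  U <- matrix(0, length(subs), length(covs), dimnames = list(subs, covs))
  for (j in unique(df$facility_id)) {
    rows_j <- which(df$facility_id == j)
    for (t in 0:tau) {
      ev <- rows_j[df$event[rows_j] == 1L & df$stop[rows_j] == t]
      if (!length(ev)) next
      risk <- intersect(oracle_at_risk(df, t, rd), rows_j)
      S0 <- sum(w[risk])
      zbar <- colSums(w[risk] * Z[risk, , drop = FALSE]) / S0
      dNj <- length(ev)
      for (r in risk) {
        dNi <- as.numeric(r %in% ev)
        U[df$subject_id[r], ] <- U[df$subject_id[r], ] +
          (Z[r, ] - zbar) * (dNi - dNj * w[r] / S0)
      }
    }
  }
  U
}

# baseline increments by day scan at given beta, alpha (named by facility)
oracle_baseline <- function(df, covs, beta, alpha, tau) {
  Z <- as.matrix(df[, covs, drop = FALSE])
  eta <- drop(Z %*% beta) + alpha[df$facility_id]
  rd <- oracle_row_days(df)
  days <- sort(unique(df$stop[df$event == 1L]))
  inc <- vapply(days, function(t) {
    risk <- oracle_at_risk(df, t, rd)
    sum(df$event == 1L & df$stop == t) / sum(exp(eta[risk]))
  }, numeric(1L))
  list(event_times = days, increments = inc)
}

# exact enumeration of the entry/censoring law: probability of exit before
# the end of the window, P(B + min(tau - B, t*) < tau)
oracle_dropout_prob <- function(tau = 365L, p_entry0 = 0.8, p_full = 0.75) {
  pB <- c(p_entry0 + (1 - p_entry0) / tau, rep((1 - p_entry0) / tau, tau - 1L))
  pT <- c(rep((1 - p_full) / tau, tau - 1L), (1 - p_full) / tau + p_full)
  # X < tau  iff  t* <= tau - 1 - B
  sum(vapply(0:(tau - 1L), function(b) {
    k <- tau - 1L - b
    if (k < 1L) return(0)
    pB[b + 1L] * sum(pT[seq_len(k)])
  }, numeric(1L)))
}

# day-by-day state machine for the COVID stage rules
oracle_stages_by_day <- function(diag_days, hosp_days, f0, f1) {
  all_diag <- sort(unique(c(diag_days, hosp_days)))
  out <- character(f1 - f0 + 1L)
  cur <- "no-COVID"
  covid_start <- NA_integer_
  last_diag <- NA_integer_
  for (d in f0:f1) {
    if (cur == "no-COVID" && d %in% all_diag) {
      cur <- "COVID"; covid_start <- d; last_diag <- d
    } else if (cur == "COVID") {
      if (d > last_diag + 20L) cur <- "post-COVID"
      if (cur == "COVID" && d %in% all_diag) last_diag <- d
    }
    if (cur == "post-COVID" && d %in% hosp_days) cur <- "late-COVID"
    out[d - f0 + 1L] <- if (cur == "COVID") {
      if (d <= covid_start + 9L) "COVID1" else "COVID2"
    } else cur
  }
  out
}

# flatten a stage timeline into per-day labels
timeline_to_days <- function(tl, f0, f1) {
  out <- character(f1 - f0 + 1L)
  for (i in seq_len(nrow(tl)))
    out[(tl$start_day[i]:tl$end_day[i]) - f0 + 1L] <- tl$stage[i]
  out
}

# small random clustered tables via the package generator
small_population <- function(seed, n_facility = 5L, mean_size = 25,
                             frailty = FALSE) {
  set.seed(seed)
  cfg <- sim_config(n_facility = n_facility, mean_size = mean_size,
                    frailty = frailty)
  simulate_population(cfg)
}

# two-subject stratum used by the hand-worked examples: both subjects at
# risk from day 0, events on day 1 (Z = 0) and day 2 (Z = 1)
symmetric_stratum <- function() {
  event_table(data.frame(
    subject_id = c("a", "a", "b"),
    facility_id = "f1",
    start = c(0L, 1L, 0L), stop = c(1L, 2L, 2L),
    event = c(1L, 0L, 1L),
    z = c(0, 0, 1)))
}

# coxph helper: shift each subject's first interval start down one day so
# that survival's (start, stop] risk sets match the entry-day-at-risk rule
coxph_frame <- function(tab) {
  df <- as.data.frame(tab)
  entry <- ave(df$start, df$subject_id, FUN = min)
  df$start2 <- ifelse(df$start == entry, df$start - 1L, df$start)
  df
}
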