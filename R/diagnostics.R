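#' Schoenfeld residuals for tied daily data
#'
#' For each time bin `(t_{k-1}, t_k]` the residual is
#' \deqn{s_k = \sum_{t_m \in bin} \Big\{\sum_{i: events\ at\ t_m} Z_i(t_m)
#'   - dN_.(t_m) \bar Z(t_m)\Big\},}
#' i.e. the covariate total of the patients with events minus the number of
#' events times the weighted average covariate of the at-risk patients.
#' Under proportional rates the residuals fluctuate around zero with no
#' trend over calendar time.
#'
#' With `scheme = "global"` (default, the usual display) the average is
#' taken over the whole at-risk population with weights
#' \eqn{\exp(Z^T\hat\beta + \hat\alpha_{G_i})}; the residuals then sum to
#' the facility-adjusted covariate score, which is only approximately zero.
#' With `scheme = "stratified"` the average is taken within the facility of
#' the event (weights \eqn{\exp(Z^T\hat\beta)}, facility effects cancel) and
#' the residuals sum to the stratified score, which is zero at the fit to
#' Newton tolerance. An unweighted average is also available.
#'
#' @param fit an [shr_fit()] result.
#' @param bins number of equal-width bins over `[0, tau]`, or an increasing
#'   vector of right bin edges (the last must be `>= tau`).
#' @param scheme `"global"`, `"stratified"` or `"unweighted"`.
#' @return data.frame of class `"residual_series"`: one row per bin with
#'   `bin`, `from`, `to`, `n_events`, `empty` and one residual column per
#'   covariate.
#' @export
schoenfeld_residuals <- function(fit, bins = 12L,
                                 scheme = c("global", "stratified",
                                            "unweighted")) {
  stopifnot(inherits(fit, "shr_fit"))
  scheme <- match.arg(scheme)
  index <- fit$index
  tau <- index$tau
  if (length(bins) == 1L) {
    edges <- round(seq(0, tau, length.out = bins + 1L))[-1L]
  } else {
    edges <- as.numeric(bins)
    if (is.unsorted(edges, strictly = TRUE) || tail(edges, 1L) < tau)
      stop("bin edges must be increasing and reach tau")
  }
  beta <- fit$beta$beta
  alpha <- fit$facility$alpha

  # per event day: covariate totals over events, dN, and weighted risk-set
  # average
  ev <- index$eday >= 0L
  ev_day <- index$eday[ev]
  Zev <- rowsum(index$Z[ev, , drop = FALSE], ev_day)
  days <- as.integer(rownames(Zev))
  dN <- as.numeric(table(factor(ev_day, levels = days)))

  if (scheme == "stratified") {
    evfac <- index$fac[ev]
    term <- matrix(0, length(days), index$p)
    for (j in sort(unique(evfac))) {
      in_j <- index$fac == j
      sub <- list(lo = index$lo[in_j], hi = index$hi[in_j], tau = tau)
      wj <- exp(drop(index$Z[in_j, , drop = FALSE] %*% beta))
      s0 <- .day_totals(sub, wj)
      s1 <- vapply(seq_len(index$p),
                   function(k) .day_totals(sub, wj * index$Z[in_j, k]),
                   numeric(tau + 1L))
      jdays <- sort(unique(ev_day[evfac == j]))
      dNj <- as.numeric(table(factor(ev_day[evfac == j], levels = jdays)))
      Zj <- rowsum(index$Z[ev, , drop = FALSE][evfac == j, , drop = FALSE],
                   ev_day[evfac == j])
      m <- match(jdays, days)
      term[m, ] <- term[m, ] + Zj -
        dNj * (s1[jdays + 1L, , drop = FALSE] / s0[jdays + 1L])
    }
    per_day <- term
  } else {
    wt <- if (scheme == "global")
      exp(drop(index$Z %*% beta) + alpha[index$fac])
    else rep.int(1, nrow(index$Z))
    s0 <- .day_totals(index, wt)
    s1 <- vapply(seq_len(index$p),
                 function(k) .day_totals(index, wt * index$Z[, k]),
                 numeric(tau + 1L))
    zbar <- s1[days + 1L, , drop = FALSE] / s0[days + 1L]
    per_day <- Zev - dN * zbar
  }

  # right bin edges: a day d belongs to the first bin with d <= edge
  bin_of <- vapply(days, function(d) which(d <= edges)[1L], integer(1L))

  res <- matrix(0, length(edges), index$p,
                dimnames = list(NULL, index$covariates))
  nev <- integer(length(edges))
  for (k in seq_along(days)) {
    res[bin_of[k], ] <- res[bin_of[k], ] + per_day[k, ]
    nev[bin_of[k]] <- nev[bin_of[k]] + dN[k]
  }
  out <- data.frame(bin = seq_along(edges),
                    from = c(0, head(edges, -1L)), to = edges,
                    n_events = nev, empty = nev == 0L)
  out <- cbind(out, as.data.frame(res))
  attr(out, "scheme") <- scheme
  class(out) <- c("residual_series", "data.frame")
  out
}

#' Observed and expected event series over calendar time
#'
#' Bins calendar days (weeks by default) and reports, per bin, the observed
#' event count `O`, the expected count under the national norm
#' `E_norm` \eqn{= \sum_{t \in bin} d\hat\mu_0(t) \sum_i Y_i(t)
#' \exp\{Z_i^T\hat\beta\}} (no facility effect: what the population would
#' experience at the average facility), and `E_fac`, the same sum including
#' \eqn{\hat\alpha_{G_i}}. Over all bins and facilities
#' `sum(O) = sum(E_norm)` by the estimation constraint. Both the ratio
#' `(O - E)/E` and the standardised `(O - E)/sqrt(E)` are emitted (based on
#' `E_norm`); under a correct model the standardised version behaves like
#' standard normal noise, so fluctuations within about \eqn{\pm 2} are
#' unremarkable.
#'
#' @param fit an [shr_fit()] result.
#' @param bin_width bin width in days (7 = weekly).
#' @param facilities optional character vector restricting the series to a
#'   subset of facilities.
#' @return data.frame with one row per bin: `bin`, `from`, `to`, `O`,
#'   `E_norm`, `E_fac`, `ratio`, `std`.
#' @export
oe_series <- function(fit, bin_width = 7L, facilities = NULL) {
  stopifnot(inherits(fit, "shr_fit"))
  index <- fit$index
  tau <- index$tau
  keep <- rep.int(TRUE, length(index$fac))
  if (!is.null(facilities)) {
    fidx <- match(facilities, index$facility_levels)
    if (anyNA(fidx)) stop("unknown facility id")
    keep <- index$fac %in% fidx
  }
  sub <- list(lo = index$lo[keep], hi = index$hi[keep], tau = tau)
  w <- exp(drop(index$Z[keep, , drop = FALSE] %*% fit$beta$beta))
  wa <- w * exp(fit$facility$alpha[index$fac[keep]])
  s0_norm <- .day_totals(sub, w)
  s0_fac <- .day_totals(sub, wa)
  dmu <- numeric(tau + 1L)
  dmu[fit$baseline$event_times + 1L] <- fit$baseline$increments

  ev <- index$eday >= 0L & keep
  o_day <- numeric(tau + 1L)
  if (any(ev)) {
    cnt <- table(index$eday[ev])
    o_day[as.integer(names(cnt)) + 1L] <- as.numeric(cnt)
  }

  day <- 0:tau
  bin <- day %/% bin_width + 1L
  O <- as.numeric(rowsum(o_day, bin))
  E_norm <- as.numeric(rowsum(dmu * s0_norm, bin))
  E_fac <- as.numeric(rowsum(dmu * s0_fac, bin))
  ub <- sort(unique(bin))
  data.frame(bin = ub,
             from = (ub - 1L) * bin_width,
             to = pmin(ub * bin_width - 1L, tau),
             O = O, E_norm = E_norm, E_fac = E_fac,
             ratio = ifelse(E_norm > 0, (O - E_norm) / E_norm, NA_real_),
             std = ifelse(E_norm > 0, (O - E_norm) / sqrt(E_norm), NA_real_))
}
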