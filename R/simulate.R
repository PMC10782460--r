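#' Simulation configuration
#'
#' Describes one study condition of the generative process used throughout
#' the package's Monte-Carlo experiments: staggered entry over a 365-day
#' window, discrete daily event times from rounded-up exponential gap times,
#' log-normal-free facility effects, and optional gamma patient frailty.
#' Defaults reproduce the base condition: 10 covariates (five standard
#' normal with variance 0.09, five Bernoulli with success probabilities
#' 0.2, 0.28, 0.36, 0.44, 0.52) with effects
#' `(0.1, -0.5, 0.3, 0.22, 0.38)` repeated twice, baseline daily rate
#' `rho0 = 0.003`, facility effects `alpha_1 = 0` and
#' `alpha_j ~ N(0, 0.2^2)` otherwise, entry at day 0 with probability 0.8
#' (else uniform on `{0, ..., tau-1}`), full potential follow-up with
#' probability 0.75 (else uniform on `{1, ..., tau}`).
#'
#' @param n_facility number of facilities `F`.
#' @param mean_size Poisson mean facility size (sizes of 0 are redrawn).
#' @param size_first,size_last fixed size overrides for the first/last
#'   facility (`NA` = drawn like the rest).
#' @param rho0 baseline daily event rate.
#' @param beta_true true covariate effects (length 10 by default).
#' @param alpha_sd standard deviation of the facility effects.
#' @param alpha_last_zero pin the last facility's true effect at 0.
#' @param frailty if `TRUE`, gap-time rates are multiplied by a patient
#'   level `W_i ~ Gamma(1, 1)` random effect.
#' @param tau study window length in days.
#' @param p_entry0 probability of entry at day 0.
#' @param p_full probability of a full potential follow-up (`t* = tau`).
#' @param scenario optional integer label attached by [scenario_config()].
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_facility = 100L, mean_size = 50,
                       size_first = NA_integer_, size_last = NA_integer_,
                       rho0 = 0.003,
                       beta_true = c(0.1, -0.5, 0.3, 0.22, 0.38,
                                     0.1, -0.5, 0.3, 0.22, 0.38),
                       alpha_sd = 0.2, alpha_last_zero = FALSE,
                       frailty = FALSE, tau = 365L,
                       p_entry0 = 0.8, p_full = 0.75,
                       scenario = NA_integer_) {
  stopifnot(n_facility >= 1L, mean_size > 0, rho0 >= 0, tau >= 1L,
            length(beta_true) == 10L)
  structure(list(n_facility = as.integer(n_facility), mean_size = mean_size,
                 size_first = size_first, size_last = size_last,
                 rho0 = rho0, beta_true = beta_true, alpha_sd = alpha_sd,
                 alpha_last_zero = alpha_last_zero, frailty = frailty,
                 tau = as.integer(tau), p_entry0 = p_entry0, p_full = p_full,
                 scenario = scenario),
            class = "sim_config")
}

#' Preset study conditions 1-6
#'
#' * Scenario 1: facility count swept over
#'   30/50/100/200/300/500/1000/2000, mean size 100.
#' * Scenario 2: 100 facilities, mean size swept from 50 to 5000.
#' * Scenario 3: as 2 with mean size 50 and the first facility fixed at 50.
#' * Scenario 4: as 3 plus Gamma(1,1) patient frailty.
#' * Scenario 5: as 3 with the last facility's effect fixed at 0 and its
#'   size swept (50 to 5000).
#' * Scenario 6: as 5 plus Gamma(1,1) patient frailty.
#'
#' @param scenario integer 1-6.
#' @param sweep the swept value (facility count for scenario 1, mean size
#'   for 2, last-facility size for 5-6; ignored for 3-4). Defaults:
#'   100 / 50 / - / - / 50 / 50.
#' @return a [sim_config()].
#' @export
scenario_config <- function(scenario, sweep = NULL) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:6) stop("unknown scenario: ", scenario)
  cfg <- switch(scenario,
    sim_config(n_facility = if (is.null(sweep)) 100L else as.integer(sweep),
               mean_size = 100),
    sim_config(mean_size = if (is.null(sweep)) 50 else sweep),
    sim_config(mean_size = 50, size_first = 50L),
    sim_config(mean_size = 50, size_first = 50L, frailty = TRUE),
    sim_config(mean_size = 50, size_first = 50L, alpha_last_zero = TRUE,
               size_last = if (is.null(sweep)) 50L else as.integer(sweep)),
    sim_config(mean_size = 50, size_first = 50L, alpha_last_zero = TRUE,
               size_last = if (is.null(sweep)) 50L else as.integer(sweep),
               frailty = TRUE))
  cfg$scenario <- scenario
  cfg
}

#' Draw one population from a study condition
#'
#' For each patient: entry day `B` (0 with probability `p_entry0`, else
#' uniform on `{0,...,tau-1}`), potential follow-up `t*` (`tau` with
#' probability `p_full`, else uniform on `{1,...,tau}`), at-risk time
#' `t = min(tau - B, t*)`, exit day `X = B + t`. Hospital admissions come
#' from a Poisson process: exponential gap times with rate
#' `rho_i = W_i * rho0 * exp(alpha_j + Z_i beta)` (`W_i = 1` without
#' frailty), each gap rounded up to the next whole day and accumulated; an
#' event whose cumulative gap equals `d` days occurs at the end of calendar
#' day `B + d`, gaps restart at the event day, and accumulation stops once
#' the running sum reaches `t` (an overshooting gap is discarded; a gap
#' landing exactly on `t` is an event on the exit day, events preceding
#' exits). Covariates are constant over follow-up.
#'
#' @param config a [sim_config()].
#' @return list with `table` (an [event_table()]) and `truth` (the drawn
#'   `alpha`, frailties `W`, per-patient entry/exit days and event counts,
#'   plus the configuration).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  F_ <- config$n_facility
  tau <- config$tau

  sizes <- rpois(F_, config$mean_size)
  while (any(sizes == 0L)) sizes[sizes == 0L] <- rpois(sum(sizes == 0L),
                                                       config$mean_size)
  if (!is.na(config$size_first)) sizes[1L] <- as.integer(config$size_first)
  if (!is.na(config$size_last)) sizes[F_] <- as.integer(config$size_last)
  n <- sum(sizes)

  alpha <- c(0, rnorm(F_ - 1L, 0, config$alpha_sd))
  if (config$alpha_last_zero && F_ > 1L) alpha[F_] <- 0

  fac_of <- rep.int(seq_len(F_), sizes)
  zc <- matrix(rnorm(5L * n, 0, 0.3), n, 5L)
  pb <- c(0.2, 0.28, 0.36, 0.44, 0.52)
  zb <- vapply(pb, function(q) rbinom(n, 1L, q), numeric(n))
  Z <- cbind(zc, zb)
  colnames(Z) <- paste0("z", 1:10)

  B <- as.integer(ifelse(runif(n) < config$p_entry0, 0L,
                         sample.int(tau, n, replace = TRUE) - 1L))
  tstar <- as.integer(ifelse(runif(n) < config$p_full, tau,
                             sample.int(tau, n, replace = TRUE)))
  t_at_risk <- pmin(tau - B, tstar)
  X <- B + t_at_risk

  W <- if (config$frailty) rexp(n) else rep.int(1, n)
  rate <- W * config$rho0 * exp(alpha[fac_of] + drop(Z %*% config$beta_true))

  # accumulate rounded-up exponential gaps until the at-risk time is reached
  ev_subj <- integer(0)
  ev_day <- integer(0)
  cum <- numeric(n)
  active <- which(rate > 0 & cum < t_at_risk)
  while (length(active)) {
    gap <- ceiling(rexp(length(active), rate[active]))
    cum[active] <- cum[active] + gap
    hit <- cum[active] <= t_at_risk[active]
    ev_subj <- c(ev_subj, active[hit])
    ev_day <- c(ev_day, B[active[hit]] + as.integer(cum[active[hit]]))
    active <- active[cum[active] < t_at_risk[active]]
  }

  # assemble counting-process rows: one row per inter-event interval plus a
  # censoring tail when the last event precedes exit
  n_ev <- tabulate(ev_subj, nbins = n)
  dt <- data.table::data.table(subj = c(ev_subj, seq_len(n)),
                               stop = c(ev_day, X),
                               event = c(rep.int(1L, length(ev_subj)),
                                         rep.int(0L, n)))
  # drop the censoring tail when an event falls exactly on the exit day
  data.table::setorder(dt, subj, stop, -event)
  dt <- dt[!(duplicated(dt, by = c("subj", "stop")) & dt$event == 0L)]
  start <- c(0L, dt$stop[-nrow(dt)])
  newsub <- c(TRUE, dt$subj[-1L] != dt$subj[-nrow(dt)])
  start[newsub] <- B[dt$subj[newsub]]

  wid_f <- nchar(as.character(F_))
  wid_s <- nchar(as.character(n))
  df <- data.frame(
    subject_id = sprintf(paste0("s%0", wid_s, "d"), dt$subj),
    facility_id = sprintf(paste0("f%0", wid_f, "d"), fac_of[dt$subj]),
    start = start, stop = dt$stop, event = dt$event,
    Z[dt$subj, , drop = FALSE])

  tab <- event_table(df)
  list(table = tab,
       truth = list(config = config, alpha = alpha, W = W,
                    beta = config$beta_true,
                    sizes = sizes, entry = B, exit = X,
                    at_risk = t_at_risk, n_events = n_ev,
                    facility_of = fac_of))
}

#' Descriptive statistics of a simulated population
#'
#' @param pop result of [simulate_population()].
#' @return list with `dropout_pct` (patients exiting before the window end,
#'   `X < tau`, in percent), `truncated_pct` (patients with at-risk time
#'   below the full window, in percent), `events_per_patient`, and
#'   `events_per_365d` (events per 365 at-risk days).
#' @export
population_stats <- function(pop) {
  tau <- pop$truth$config$tau
  list(dropout_pct = 100 * mean(pop$truth$exit < tau),
       truncated_pct = 100 * mean(pop$truth$at_risk < tau),
       events_per_patient = mean(pop$truth$n_events),
       events_per_365d = 365 * sum(pop$truth$n_events) /
         sum(pop$truth$at_risk))
}
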