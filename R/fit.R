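#' Fit the clustered recurrent-event proportional-rates model
#'
#' The full two-part procedure: (1) estimate the covariate effects from the
#' facility-stratified Breslow partial likelihood; (2) with those effects
#' fixed, estimate the non-parametric calendar-time baseline and the
#' facility effects by the constrained fixed-point iteration (see
#' [fit_alpha()]). Naive and sandwich variances are attached for both sets
#' of parameters.
#'
#' @param table an [event_table()] (or a data.frame accepted by it).
#' @param tau study window end; default the latest stop day.
#' @param tol_beta,max_iter_beta Newton controls for the covariate fit.
#' @param tol_alpha,max_iter_alpha fixed-point controls.
#' @param ci_level Wald confidence level used by [summary.shr_fit()] and the
#'   CSV writers.
#' @return an object of class `"shr_fit"` with components
#'   `beta` (an `"shr_beta"`), `beta_naive_cov`, `beta_sandwich_cov`,
#'   `facility` (a `"facility_effects"`), `facility_se` (naive and sandwich
#'   per-facility standard errors), `baseline` (a `"baseline_rate"`),
#'   `index` (the [risk_index()] used), and `settings`.
#' @examples
#' cfg <- scenario_config(3)
#' cfg$n_facility <- 5; cfg$mean_size <- 20; cfg$size_first <- NA
#' set.seed(1)
#' pop <- simulate_population(cfg)
#' fit <- shr_fit(pop$table)
#' fit
#' @export
shr_fit <- function(table, tau = NULL, tol_beta = 1e-8, max_iter_beta = 50L,
                    tol_alpha = 1e-6, max_iter_alpha = 1000L,
                    ci_level = 0.95) {
  index <- risk_index(table, tau = tau)
  bfit <- fit_beta(index, tol = tol_beta, max_iter = max_iter_beta)
  naive_cov <- solve(bfit$information)
  Uh <- cpp_subject_scores(index$lo, index$hi, index$fac - 1L,
                           index$subj - 1L, index$eday, index$Z,
                           bfit$beta, index$n_facility, index$n, index$tau)
  sand_cov <- naive_cov %*% crossprod(Uh) %*% naive_cov
  dimnames(naive_cov) <- dimnames(sand_cov) <-
    list(index$covariates, index$covariates)

  fe <- fit_alpha(index, bfit$beta, tol = tol_alpha,
                  max_iter = max_iter_alpha)
  se <- alpha_se(fe)

  structure(list(
    beta = bfit,
    beta_naive_cov = naive_cov,
    beta_sandwich_cov = sand_cov,
    subject_scores = Uh,
    facility = fe,
    facility_se = se,
    baseline = fe$baseline,
    index = index,
    settings = list(tau = index$tau, tol_beta = tol_beta,
                    tol_alpha = tol_alpha, ci_level = ci_level)
  ), class = "shr_fit")
}

#' @export
print.shr_fit <- function(x, ...) {
  cat("proportional-rates model fit\n")
  cat(sprintf("  %d subjects, %d facilities, %d events on %d distinct days\n",
              x$index$n, x$index$n_facility, sum(x$facility$O_fac),
              length(x$index$event_times)))
  est <- x$beta$beta
  tab <- cbind(estimate = est,
               `naive se` = sqrt(diag(x$beta_naive_cov)),
               `robust se` = sqrt(diag(x$beta_sandwich_cov)))
  print(round(tab, 4L))
  cat(sprintf("  facility effects: %d fixed-point iterations, final C = %.8f\n",
              x$facility$n_iter, tail(x$facility$C_history, 1L)))
  cat(sprintf("  sum(O) = %.2f, sum(E) = %.2f\n",
              sum(x$facility$O_fac), sum(x$facility$E_fac)))
  invisible(x)
}

#' @export
coef.shr_fit <- function(object, ...) object$beta$beta

#' @param type `"sandwich"` (default) or `"naive"`.
#' @rdname shr_fit
#' @export
vcov.shr_fit <- function(object, type = c("sandwich", "naive"), ...) {
  switch(match.arg(type),
         sandwich = object$beta_sandwich_cov,
         naive = object$beta_naive_cov)
}

#' Summarise a fitted model
#'
#' @param object an [shr_fit()] result.
#' @param ci_level Wald confidence level (default from the fit settings).
#' @param ... unused.
#' @return list with a coefficient table (`coefficients`) and a per-facility
#'   table (`facility`) carrying O, E, alpha, SHR, both standard errors and
#'   Wald intervals for alpha.
#' @export
summary.shr_fit <- function(object, ci_level = NULL, ...) {
  if (is.null(ci_level)) ci_level <- object$settings$ci_level
  est <- object$beta$beta
  nse <- sqrt(diag(object$beta_naive_cov))
  sse <- sqrt(diag(object$beta_sandwich_cov))
  ci <- wald_ci(est, sse, ci_level)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      naive_se = unname(nse), robust_se = unname(sse),
                      lower = ci[, 1L], upper = ci[, 2L],
                      row.names = NULL)
  fe <- object$facility
  se <- object$facility_se
  aci <- wald_ci(fe$alpha, se$sandwich, ci_level)
  fac <- data.frame(facility_id = names(fe$alpha),
                    O = unname(fe$O_fac), E = unname(fe$E_fac),
                    alpha = unname(fe$alpha), shr = unname(fe$shr),
                    naive_se = unname(se$naive),
                    robust_se = unname(se$sandwich),
                    lower = unname(aci[, 1L]), upper = unname(aci[, 2L]),
                    zero_event = unname(fe$zero_event),
                    row.names = NULL)
  out <- list(coefficients = coefs, facility = fac, ci_level = ci_level,
              loglik = object$beta$loglik,
              C_final = tail(object$facility$C_history, 1L))
  class(out) <- "summary.shr_fit"
  out
}

#' @export
print.summary.shr_fit <- function(x, ...) {
  cat("coefficients:\n")
  print(x$coefficients, digits = 4L)
  cat("\nfacilities (first 10):\n")
  print(utils::head(x$facility, 10L), digits = 4L)
  invisible(x)
}
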