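#' Stratified Breslow score, information and log partial likelihood
#'
#' Evaluates, at a given coefficient vector, the facility-stratified
#' estimating function
#' \deqn{U(\beta)=\sum_j \sum_m \{\sum_{i \in F_{j,m}} Z_i(t_m) -
#'   dN_j(t_m)\bar Z_j(t_m)\},}
#' the observed information
#' \eqn{I(\beta)=\sum_j\sum_m dN_j(t_m)\{S^{(2)}_j/S^{(0)}_j -
#' \bar Z_j \bar Z_j^T\}} and the Breslow log partial likelihood. Ties within
#' a facility-day share the same risk-set denominator (Breslow handling);
#' strata with no events contribute nothing.
#'
#' @param index a [risk_index()].
#' @param beta numeric coefficient vector of length `p`.
#' @return list with components `score` (length `p`), `information`
#'   (`p x p`), `loglik` (scalar).
#' @export
score_beta <- function(index, beta) {
  stopifnot(inherits(index, "risk_index"))
  beta <- as.numeric(beta)
  if (length(beta) != index$p)
    stop("beta must have length ", index$p)
  if (any(!is.finite(beta))) stop("beta contains non-finite entries")
  out <- cpp_score(index$lo, index$hi, index$fac - 1L, index$eday,
                   index$Z, beta, index$n_facility, index$tau)
  out$score <- drop(out$score)
  dimnames(out$information) <- list(index$covariates, index$covariates)
  names(out$score) <- index$covariates
  out
}

#' Fit the covariate effects of the stratified proportional-rates model
#'
#' Newton-Raphson with step-halving on the Breslow log partial likelihood of
#' the facility-stratified model. Facility effects and the baseline are
#' absorbed by the stratification, so `beta` is estimated before (and
#' independently of) the facility-effect iteration.
#'
#' @param index a [risk_index()].
#' @param init starting value (default zero vector).
#' @param tol convergence tolerance on `max(abs(U(beta)))`.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `"shr_beta"`: list with `beta`, `information`,
#'   `loglik`, `n_iter`, `converged`.
#' @export
fit_beta <- function(index, init = NULL, tol = 1e-8, max_iter = 50L) {
  stopifnot(inherits(index, "risk_index"))
  p <- index$p
  if (p < 1L) stop("at least one covariate is required")
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  if (length(beta) != p) stop("init must have length ", p)

  sc <- score_beta(index, beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    if (max(abs(sc$score)) <= tol) { converged <- TRUE; break }
    iter <- iter + 1L
    step <- tryCatch(solve(sc$information, sc$score), error = function(e) {
      bad <- .collinear_columns(sc$information)
      stop("singular information matrix; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    })
    # step-halving: never accept a decrease of the log partial likelihood
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      sc_new <- score_beta(index, cand)
      if (sc_new$loglik >= sc$loglik - 1e-12 * abs(sc$loglik)) break
      lambda <- lambda / 2
      if (lambda < 2^-20) break
    }
    beta <- beta + lambda * step
    sc <- sc_new
    if (any(abs(beta) > 50)) break   # diverging estimate (monotone likelihood)
  }
  if (!converged && max(abs(sc$score)) <= tol) converged <- TRUE
  if (!converged)
    warning("Newton-Raphson did not converge: max|U| = ",
            format(max(abs(sc$score))), " after ", iter, " iterations")
  structure(list(beta = setNames(drop(beta), index$covariates),
                 information = sc$information,
                 loglik = sc$loglik, score = sc$score,
                 n_iter = iter, converged = converged),
            class = "shr_beta")
}

.collinear_columns <- function(info) {
  qr_ <- qr(info)
  cols <- colnames(info)
  if (is.null(cols)) cols <- paste0("Z", seq_len(ncol(info)))
  if (qr_$rank < ncol(info))
    cols[qr_$pivot[(qr_$rank + 1L):ncol(info)]]
  else cols
}

#' @export
print.shr_beta <- function(x, ...) {
  cat("stratified proportional-rates fit:",
      length(x$beta), "coefficients,",
      x$n_iter, "Newton iterations",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$beta)
  invisible(x)
}

#' Nelson-Aalen baseline rate on the event-day grid
#'
#' Computes \eqn{d\hat\mu_0(t_m) = dN_.(t_m) / S^{(0)}(t_m)} with
#' \eqn{S^{(0)}(t) = \sum_i Y_i(t)\exp\{Z_i^T(t)\beta + \alpha_{G_i}\}}, and
#' zero off the grid of observed event days.
#'
#' @param index a [risk_index()].
#' @param beta covariate coefficients.
#' @param alpha per-facility effects, in the order of
#'   `index$facility_levels`; a scalar is recycled.
#' @return an object of class `"baseline_rate"`: list with `event_times`,
#'   `increments` (one per event day, all positive) and the window `tau`.
#' @export
baseline_rate <- function(index, beta, alpha = 0) {
  stopifnot(inherits(index, "risk_index"))
  alpha <- rep_len(as.numeric(alpha), index$n_facility)
  wt <- exp(drop(index$Z %*% as.numeric(beta)) + alpha[index$fac])
  s0 <- .day_totals(index, wt)
  s0m <- s0[index$event_times + 1L]
  if (any(s0m <= 0)) stop("risk-set total is zero at an event day")
  structure(list(event_times = index$event_times,
                 increments = index$dN_total / s0m,
                 tau = index$tau),
            class = "baseline_rate")
}

#' @export
print.baseline_rate <- function(x, ...) {
  cat(sprintf("baseline rate: %d jumps on [0, %d], total %.4f\n",
              length(x$event_times), x$tau, sum(x$increments)))
  invisible(x)
}

#' Observed and expected event counts
#'
#' Expected counts accumulate the baseline increments over each subject's
#' at-risk days, scaled by \eqn{\exp\{Z_i^T(t)\hat\beta\}}. Facility effects
#' do not enter `E` (they are what `O/E` measures).
#'
#' @param index a [risk_index()].
#' @param baseline a [baseline_rate()] on the same day grid.
#' @param beta covariate coefficients.
#' @return list with per-facility vectors `O_fac`, `E_fac` (named by
#'   facility) and per-subject vectors `O_subj`, `E_subj` (named by subject).
#' @export
expected_events <- function(index, baseline, beta) {
  stopifnot(inherits(index, "risk_index"), inherits(baseline, "baseline_rate"))
  if (!identical(as.integer(baseline$event_times), index$event_times))
    stop("baseline grid does not match the table's event days")
  dmu <- numeric(index$tau + 1L)
  dmu[baseline$event_times + 1L] <- baseline$increments
  w <- exp(drop(index$Z %*% as.numeric(beta)))
  e_row <- w * .row_range_sums(index, dmu)
  E_fac <- .sum_by(e_row, index$fac, index$n_facility, index$facility_levels)
  E_subj <- .sum_by(e_row, index$subj, index$n, index$subject_levels)
  has_ev <- index$eday >= 0L
  O_fac <- .sum_by(as.numeric(has_ev), index$fac, index$n_facility,
                   index$facility_levels)
  O_subj <- .sum_by(as.numeric(has_ev), index$subj, index$n,
                    index$subject_levels)
  list(O_fac = O_fac, E_fac = E_fac, O_subj = O_subj, E_subj = E_subj)
}

.sum_by <- function(x, g, ng, labels) {
  out <- numeric(ng)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  names(out) <- labels
  out
}

#' Fixed-point estimation of facility effects
#'
#' Holding `beta` fixed, alternates (a) the Nelson-Aalen baseline at the
#' current facility effects with (b) the explicit update
#' \eqn{\exp(\hat\alpha_j^{(s+1)}) = C^{(s)} O_j / E_j^{(s)}}, where
#' \eqn{C^{(s)} = \sum_k E_k^{(s)} / \sum_k O_k} recentres the effects so
#' that \eqn{\sum_j O_j = \sum_j E_j} holds at every iteration (and the
#' population-level standardised ratio is 1). Iteration stops when the
#' largest absolute change in \eqn{\hat\alpha_j} over facilities with events
#' is at most `tol`. Facilities with no events are pinned at the sentinel
#' \eqn{\alpha_j = -10} (their subjects still contribute to the risk sets,
#' with weight \eqn{e^{-10}}, and to the expected counts) and are excluded
#' from the convergence check.
#'
#' @param index a [risk_index()].
#' @param beta covariate coefficients (typically from [fit_beta()]).
#' @param tol convergence tolerance on `max(abs(diff(alpha)))`.
#' @param max_iter maximum fixed-point iterations.
#' @param sentinel value assigned to zero-event facilities.
#' @return an object of class `"facility_effects"`: list with `alpha`,
#'   `O_fac`, `E_fac`, `shr` (= O/E), per-subject `O_subj`/`E_subj`,
#'   `zero_event` flags, the scaling history `C_history`, the profile
#'   log-likelihood history, iteration count, convergence flag, and the final
#'   baseline (`baseline`).
#' @export
fit_alpha <- function(index, beta, tol = 1e-6, max_iter = 1000L,
                      sentinel = -10) {
  stopifnot(inherits(index, "risk_index"))
  out <- cpp_fixed_point(index$lo, index$hi, index$fac - 1L, index$subj - 1L,
                         index$eday, index$Z, as.numeric(beta),
                         index$n_facility, index$n, index$tau,
                         tol, as.integer(max_iter), sentinel)
  fl <- index$facility_levels
  alpha <- setNames(drop(out$alpha), fl)
  O_fac <- setNames(drop(out$O_fac), fl)
  E_fac <- setNames(drop(out$E_fac), fl)
  if (!out$converged)
    warning("fixed-point iteration did not converge in ", max_iter,
            " iterations (last max|delta| = ",
            format(tail(out$delta_history, 1L)), ")")
  shr <- ifelse(O_fac > 0, O_fac / E_fac, 0)
  first_row <- !duplicated(index$subj)
  subj_fac <- character(index$n)
  subj_fac[index$subj[first_row]] <- fl[index$fac[first_row]]
  structure(list(
    alpha = alpha, O_fac = O_fac, E_fac = E_fac, shr = shr,
    O_subj = setNames(drop(out$O_subj), index$subject_levels),
    E_subj = setNames(drop(out$E_subj), index$subject_levels),
    subject_facility = setNames(subj_fac, index$subject_levels),
    zero_event = O_fac == 0,
    C_history = out$C_history,
    loglik_history = out$loglik_history,
    delta_history = out$delta_history,
    n_iter = out$n_iter, converged = out$converged,
    sentinel = sentinel,
    baseline = structure(list(
      event_times = index$event_times,
      increments = drop(out$dmu)[index$event_times + 1L],
      tau = index$tau), class = "baseline_rate")
  ), class = "facility_effects")
}

#' @export
print.facility_effects <- function(x, ...) {
  cat(sprintf(
    "facility effects: %d facilities (%d with no events), %d iterations%s, final C = %.8f\n",
    length(x$alpha), sum(x$zero_event), x$n_iter,
    if (x$converged) "" else " [NOT converged]",
    tail(x$C_history, 1L)))
  invisible(x)
}
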