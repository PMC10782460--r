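#' Sandwich (robust) covariance for the covariate effects
#'
#' Computes \eqn{\hat V = I(\hat\beta)^{-1} \sum_i \hat U_i^{\otimes 2}
#' I(\hat\beta)^{-1}} where \eqn{\hat U_i} sums, over the event days of
#' subject `i`'s facility on which the subject is at risk,
#' \eqn{\{Z_i(t_m)-\bar Z_{G_i}(t_m)\}\{dN_i(t_m) -
#' dN_{G_i}(t_m)\exp(Z_i^T\hat\beta)/\hat S^{(0)}_{G_i}(t_m)\}}. This is the
#' marginal-rate-model variance, robust to within-subject dependence of the
#' event process.
#'
#' @param index a [risk_index()].
#' @param fit an `"shr_beta"` object from [fit_beta()].
#' @return the `p x p` sandwich covariance matrix.
#' @export
sandwich_beta <- function(index, fit) {
  stopifnot(inherits(index, "risk_index"), inherits(fit, "shr_beta"))
  Iinv <- solve(fit$information)
  Uh <- cpp_subject_scores(index$lo, index$hi, index$fac - 1L,
                           index$subj - 1L, index$eday, index$Z,
                           fit$beta, index$n_facility, index$n, index$tau)
  V <- Iinv %*% crossprod(Uh) %*% Iinv
  dimnames(V) <- list(index$covariates, index$covariates)
  V
}

#' Naive and sandwich standard errors for the facility effects
#'
#' The naive standard error of \eqn{\hat\alpha_j} is \eqn{1/\sqrt{O_j}}
#' (the inverse observed information of the per-facility estimating
#' equation). The sandwich version is \eqn{\sqrt{V_j}} with
#' \deqn{V_j=\sum_{i:G_i=j}\left(O_{ij}-E_{ij}\frac{O_j}{E_j}\right)^2 /
#'   O_j^2,} which is robust to within-subject correlation. Both treat
#' \eqn{\hat\beta} and the baseline as fixed: in profiling applications the
#' population is much larger than any facility, so their sampling
#' variability is negligible relative to that of \eqn{\hat\alpha_j}.
#' Facilities with no events get `NA` for both (their effect is the
#' sentinel, not an estimate).
#'
#' @param fe a `"facility_effects"` object from [fit_alpha()], or any list
#'   with entries `O_fac`, `E_fac`, `O_subj`, `E_subj` (per-facility and
#'   per-subject observed/expected counts).
#' @param fac_of_subj facility label for every subject (in the order of
#'   `O_subj`); defaults to the map stored by [fit_alpha()].
#' @return list with per-facility vectors `naive` and `sandwich`.
#' @export
alpha_se <- function(fe, fac_of_subj = NULL) {
  if (is.null(fac_of_subj)) fac_of_subj <- fe$subject_facility
  if (is.null(fac_of_subj))
    stop("fac_of_subj is required when `fe` does not carry a subject map")
  O_fac <- fe$O_fac
  E_fac <- fe$E_fac
  naive <- ifelse(O_fac > 0, 1 / sqrt(O_fac), NA_real_)
  # V_j from per-subject observed/expected counts
  ratio <- ifelse(E_fac > 0, O_fac / E_fac, 0)
  fidx <- match(fac_of_subj, names(O_fac))
  resid <- fe$O_subj - fe$E_subj * ratio[fidx]
  V <- .sum_by(resid^2, fidx, length(O_fac), names(O_fac)) /
    ifelse(O_fac > 0, O_fac^2, NA_real_)
  sandwich <- ifelse(O_fac > 0, sqrt(V), NA_real_)
  list(naive = naive, sandwich = sandwich)
}

#' Wald confidence interval
#'
#' @param estimate,se numeric vectors (recycled).
#' @param level confidence level in (0, 1).
#' @return two-column matrix of lower and upper limits; `se = 0` gives a
#'   degenerate interval at the estimate.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single number in (0, 1)")
  if (any(se < 0, na.rm = TRUE)) stop("negative standard error")
  z <- qnorm((1 + level) / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}
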