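#' Whole-population expected count for direct standardisation
#'
#' \eqn{E^{(j)*}} is the expected number of events in the *whole* population
#' if every patient were treated at facility `j`'s estimated rate:
#' \deqn{E^{(j)*} = \sum_i \sum_m Y_i(t_m)\, d\hat\mu_0(t_m)
#'   \exp\{Z_i^T(t_m)\hat\beta + \hat\alpha_j\}.}
#' Computed by actual summation over the population, not via the indirect
#' identity, so that the equivalence of the two standardisations can be
#' verified numerically.
#'
#' @param index a [risk_index()].
#' @param baseline a [baseline_rate()].
#' @param beta covariate coefficients.
#' @param alpha_j scalar facility effect (may be a vector, vectorised over
#'   facilities).
#' @return numeric vector of the same length as `alpha_j`.
#' @export
direct_expected <- function(index, baseline, beta, alpha_j) {
  stopifnot(inherits(index, "risk_index"), inherits(baseline, "baseline_rate"))
  dmu <- numeric(index$tau + 1L)
  dmu[baseline$event_times + 1L] <- baseline$increments
  w <- exp(drop(index$Z %*% as.numeric(beta)))
  base_total <- sum(w * .row_range_sums(index, dmu))
  exp(as.numeric(alpha_j)) * base_total
}

#' Indirect and direct standardised ratios
#'
#' The indirect ratio is \eqn{O_j/E_j}; the direct one is
#' \eqn{E^{(j)*}/\sum_k O_k}. Under the \eqn{\sum O = \sum E} constraint
#' used for estimation the two coincide, so the fitted ratios inherit both
#' interpretations. Facilities with no events report an indirect ratio of 0
#' and are flagged.
#'
#' @param fit an [shr_fit()] result.
#' @return data.frame of class `"standardised_measures"` with columns
#'   `facility_id`, `O`, `E`, `alpha`, `shr_indirect`, `whole_pop_expected`
#'   (\eqn{E^{(j)*}}), `shr_direct`, `equivalence_gap`
#'   (`shr_indirect - shr_direct`) and `zero_event`.
#' @export
standardise <- function(fit) {
  stopifnot(inherits(fit, "shr_fit"))
  fe <- fit$facility
  estar <- direct_expected(fit$index, fit$baseline, fit$beta$beta, fe$alpha)
  o_tot <- sum(fe$O_fac)
  out <- data.frame(
    facility_id = names(fe$alpha),
    O = unname(fe$O_fac), E = unname(fe$E_fac),
    alpha = unname(fe$alpha),
    shr_indirect = unname(fe$shr),
    whole_pop_expected = unname(estar),
    shr_direct = unname(estar / o_tot),
    zero_event = unname(fe$zero_event),
    row.names = NULL)
  out$equivalence_gap <- out$shr_indirect - out$shr_direct
  class(out) <- c("standardised_measures", "data.frame")
  out
}

#' Flag facilities excluded from profiling displays
#'
#' Funnel plots and SHR histograms conventionally drop facilities whose
#' expected count is extreme or whose observed count is zero, where the
#' ratio is unstable or dominated by scale. Adds a logical
#' `display_excluded` column: `TRUE` when `E > e_max`, `E < e_min` or
#' `O == 0`.
#'
#' @param measures output of [standardise()] (any data.frame with `O`, `E`).
#' @param e_min,e_max expected-count display window (defaults 5 and 800).
#' @return `measures` with the `display_excluded` column appended.
#' @export
profiling_flag <- function(measures, e_min = 5, e_max = 800) {
  stopifnot(all(c("O", "E") %in% names(measures)))
  measures$display_excluded <-
    measures$E > e_max | measures$E < e_min | measures$O == 0
  measures
}

#' Recentre facility effects under an alternative reporting constraint
#'
#' Estimation always uses the \eqn{\sum O = \sum E} constraint (the only one
#' under which indirect and direct standardisation coincide), but reports
#' can recentre the effects for display: shifting every \eqn{\alpha_j} by a
#' constant and scaling the baseline by its exponential leaves every SHR and
#' every expected count unchanged.
#'
#' @param fit an [shr_fit()] result.
#' @param constraint `"sum_oe"` (no change), `"median"`
#'   (median of the non-sentinel effects becomes 0) or `"size_weighted"`
#'   (\eqn{\sum_j n_j \alpha_j = 0} over non-sentinel facilities).
#' @return list with `alpha` (recentred), `shift` (the constant subtracted)
#'   and `baseline` (increments multiplied by `exp(shift)`).
#' @export
recentre_alpha <- function(fit, constraint = c("sum_oe", "median",
                                               "size_weighted")) {
  constraint <- match.arg(constraint)
  fe <- fit$facility
  keep <- !fe$zero_event
  shift <- switch(constraint,
    sum_oe = 0,
    median = median(fe$alpha[keep]),
    size_weighted = {
      n_j <- table(factor(fe$subject_facility, levels = names(fe$alpha)))
      sum(n_j[keep] * fe$alpha[keep]) / sum(n_j[keep])
    })
  base <- fit$baseline
  base$increments <- base$increments * exp(shift)
  list(alpha = fe$alpha - shift, shift = shift, baseline = base)
}
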