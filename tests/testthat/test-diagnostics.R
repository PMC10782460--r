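test_that("a single event day gives the hand-computed residual", {
  # two subjects at risk, Z in {0, 1}, event on the Z = 1 subject,
  # beta-hat = alpha-hat = 0: residual 1 - 1/2
  tab <- event_table(data.frame(
    subject_id = c("a", "b"), facility_id = "f1",
    start = 0L, stop = c(10L, 7L), event = c(0L, 1L),
    z = c(0, 1)))
  idx <- risk_index(tab)
  fit <- list(index = idx,
              beta = list(beta = setNames(0, "z")),
              facility = list(alpha = setNames(0, "f1")))
  class(fit) <- "shr_fit"
  res <- schoenfeld_residuals(fit, bins = 1L)
  expect_equal(res$z, 0.5)
  expect_equal(res$n_events, 1L)
})

test_that("residuals over one bin equal the pooled score", {
  pop <- small_population(15, n_facility = 5L, mean_size = 20)
  fit <- shr_fit(pop$table)
  # stratified weighting: the residual total IS the stratified score, zero
  # at the fit up to Newton tolerance
  res_s <- schoenfeld_residuals(fit, bins = 1L, scheme = "stratified")
  expect_true(all(abs(res_s[, fit$index$covariates]) < 1e-7))
  # global weighting (with alpha-hat): approximately zero, small relative
  # to the score's own scale sqrt(diag I)
  res_g <- schoenfeld_residuals(fit, bins = 1L, scheme = "global")
  scale_ <- sqrt(diag(fit$beta$information))
  expect_true(all(abs(res_g[, fit$index$covariates]) / scale_ < 3))
})

test_that("binned residuals sum to the one-bin residuals and flag empty bins", {
  pop <- small_population(16, n_facility = 4L, mean_size = 15)
  fit <- shr_fit(pop$table)
  covs <- fit$index$covariates
  r1 <- schoenfeld_residuals(fit, bins = 1L)
  r12 <- schoenfeld_residuals(fit, bins = 12L)
  expect_equal(colSums(r12[, covs]), colSums(r1[, covs]), tolerance = 1e-10)
  expect_equal(sum(r12$n_events), sum(fit$index$dN_total))
  expect_true(all(r12$empty == (r12$n_events == 0L)))
})

test_that("proportional data show no residual trend across bins", {
  pop <- small_population(99, n_facility = 20L, mean_size = 60)
  fit <- shr_fit(pop$table)
  res <- schoenfeld_residuals(fit, bins = 26L)
  # per-event-average residual regressed on bin index: slope within 3 SEs
  for (cv in c("z1", "z6")) {
    y <- res[[cv]][!res$empty] / res$n_events[!res$empty]
    x <- res$bin[!res$empty]
    sl <- summary(stats::lm(y ~ x))$coefficients
    expect_lt(abs(sl["x", "t value"]), 3)
  }
})

test_that("observed/expected series respects the constraint and partitions by facility", {
  pop <- small_population(47, n_facility = 5L, mean_size = 25)
  fit <- shr_fit(pop$table)
  oe <- oe_series(fit, bin_width = 7L)
  expect_equal(sum(oe$O), sum(fit$facility$O_fac))
  expect_equal(sum(oe$O), sum(oe$E_norm), tolerance = 1e-8)
  # with facility effects included, the daily expected count reproduces the
  # observed total exactly (that is what the baseline estimator encodes)
  expect_equal(sum(oe$E_fac), sum(oe$O), tolerance = 1e-8)
  # restricting to one facility recovers its O_j and E_j totals
  j <- names(fit$facility$O_fac)[2L]
  oej <- oe_series(fit, bin_width = 7L, facilities = j)
  expect_equal(sum(oej$O), unname(fit$facility$O_fac[j]))
  expect_equal(sum(oej$E_norm), unname(fit$facility$E_fac[j]),
               tolerance = 1e-8)
  expect_error(oe_series(fit, facilities = "nope"), "unknown facility")
})

test_that("standardised weekly deviations look like noise under the model", {
  pop <- small_population(61, n_facility = 12L, mean_size = 80)
  fit <- shr_fit(pop$table)
  oe <- oe_series(fit, bin_width = 7L)
  z <- oe$std[oe$E_norm >= 5]
  expect_gt(mean(abs(z) <= 2), 0.85)
})

test_that("COVID stage intervals replay the worked examples", {
  tl <- covid_stages(100L, followup = c(0L, 200L))
  expect_identical(tl$stage,
                   c("no-COVID", "COVID1", "COVID2", "post-COVID"))
  expect_identical(tl$start_day, c(0L, 100L, 110L, 121L))
  expect_identical(tl$end_day, c(99L, 109L, 120L, 200L))
  # a repeat diagnosis resets the 21-day clock
  tl2 <- covid_stages(c(100L, 115L), followup = c(0L, 200L))
  expect_identical(tl2$start_day[tl2$stage == "post-COVID"], 136L)
  # no diagnoses: a single no-COVID interval
  tl0 <- covid_stages(followup = c(10L, 50L))
  expect_identical(tl0$stage, "no-COVID")
  expect_identical(c(tl0$start_day, tl0$end_day), c(10L, 50L))
  # COVID-coded admission while post-COVID: late-COVID, absorbing
  tl3 <- covid_stages(100L, covid_hosp_days = c(160L, 180L),
                      followup = c(0L, 200L))
  expect_identical(tl3$stage[5L], "late-COVID")
  expect_identical(tl3$start_day[5L], 160L)
  expect_identical(tl3$end_day[5L], 200L)
  expect_warning(covid_stages(c(100L, 300L), followup = c(0L, 200L)),
                 "ignored")
})

test_that("stage intervals agree with a day-by-day state machine", {
  set.seed(33)
  for (case in 1:25) {
    f1 <- sample(150:400, 1L)
    nd <- sample(0:6, 1L)
    diag_days <- sort(sample(0:f1, nd))
    nh <- sample(0:3, 1L)
    hosp_days <- sort(sample(0:f1, nh))
    tl <- covid_stages(diag_days, hosp_days, followup = c(0L, f1))
    # partition: no gaps, no overlaps
    expect_identical(tl$start_day[1L], 0L)
    expect_identical(tl$end_day[nrow(tl)], f1)
    if (nrow(tl) > 1L)
      expect_identical(tl$start_day[-1L], tl$end_day[-nrow(tl)] + 1L)
    expect_identical(timeline_to_days(tl, 0L, f1),
                     oracle_stages_by_day(diag_days, hosp_days, 0L, f1))
  }
})

test_that("multi-patient stage tables stack per-patient timelines", {
  pats <- data.frame(subject_id = c("p1", "p2"),
                     follow_start = c(0L, 30L), follow_end = c(200L, 300L))
  dg <- data.frame(subject_id = c("p1", "p2", "p2"),
                   day = c(100L, 60L, 200L),
                   covid_hosp = c(FALSE, FALSE, TRUE))
  st <- covid_stage_table(pats, dg)
  expect_identical(sort(unique(st$subject_id)), c("p1", "p2"))
  p2 <- st[st$subject_id == "p2", ]
  expect_true("late-COVID" %in% p2$stage)
  expect_identical(p2$start_day[p2$stage == "late-COVID"], 200L)
})
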