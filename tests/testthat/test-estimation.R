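test_that("a symmetric two-subject stratum gives a zero score and beta-hat 0", {
  idx <- risk_index(symmetric_stratum())
  sc <- score_beta(idx, 0)
  expect_equal(unname(sc$score), 0)
  fit <- fit_beta(idx)
  expect_equal(unname(fit$beta), 0)
  expect_true(fit$converged)
})

test_that("a stratum with identical covariates contributes nothing to the score", {
  tab <- event_table(data.frame(
    subject_id = c("a", "b", "c"), facility_id = c("f1", "f1", "f2"),
    start = 0L, stop = c(5L, 9L, 9L), event = 1L,
    z = c(2, 2, 0.5)))
  idx <- risk_index(tab)
  for (b in c(-1, 0, 0.7)) {
    # facility f1's subjects share z = 2 -> its terms vanish; f2 has a
    # single subject, also vanishing, so the total score is 0 for every beta
    expect_equal(unname(score_beta(idx, b)$score), 0, tolerance = 1e-12)
  }
})

test_that("score and information match numerical derivatives of the summed log likelihood", {
  pop <- small_population(31, n_facility = 2L, mean_size = 10)
  df <- as.data.frame(pop$table)
  covs <- attr(pop$table, "covariates")[1:3]
  tab <- event_table(df[, c("subject_id", "facility_id", "start", "stop",
                            "event", covs)])
  idx <- risk_index(tab)
  set.seed(99)
  for (k in 1:5) {
    b <- rnorm(3, 0, 0.3)
    sc <- score_beta(idx, b)
    expect_equal(sc$loglik, oracle_loglik(df, covs, b, idx$tau),
                 tolerance = 1e-10)
    fd <- oracle_score_fd(df, covs, b, idx$tau)
    expect_equal(unname(sc$score), fd, tolerance = 1e-6)
  }
})

test_that("Newton solution matches a cyclic one-dimensional maximiser of the same likelihood", {
  pop <- small_population(7, n_facility = 3L, mean_size = 12)
  df <- as.data.frame(pop$table)
  covs <- attr(pop$table, "covariates")[c(1, 7)]
  tab <- event_table(df[, c("subject_id", "facility_id", "start", "stop",
                            "event", covs)])
  idx <- risk_index(tab)
  fit <- fit_beta(idx)
  # coordinate-wise golden-section refinement of the oracle likelihood
  b <- c(0, 0)
  for (cycle in 1:8) {
    for (k in 1:2) {
      f1 <- function(x) {
        bb <- b; bb[k] <- x
        oracle_loglik(df, covs, bb, idx$tau)
      }
      b[k] <- stats::optimize(f1, interval = b[k] + c(-2, 2),
                              maximum = TRUE, tol = 1e-7)$maximum
    }
  }
  expect_equal(unname(fit$beta), b, tolerance = 1e-4)
})

test_that("stratified fit agrees with survival's Breslow partial likelihood", {
  skip_if_not_installed("survival")
  pop <- small_population(12, n_facility = 6L, mean_size = 20)
  fit <- shr_fit(pop$table)
  df <- coxph_frame(pop$table)
  covs <- attr(pop$table, "covariates")
  fml <- stats::as.formula(paste(
    "survival::Surv(start2, stop, event) ~",
    paste(covs, collapse = "+"), "+ survival::strata(facility_id)"))
  cx <- survival::coxph(fml, data = df, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(cx)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(fit, "naive")))),
               unname(sqrt(diag(vcov(cx)))), tolerance = 1e-6)
})

test_that("baseline increments are occurrence over weighted exposure", {
  # ten subjects at risk around day 4, one event, null covariate
  tab <- event_table(data.frame(
    subject_id = sprintf("s%02d", 1:10), facility_id = "f1",
    start = 0L, stop = c(4L, rep(10L, 9L)),
    event = c(1L, rep(0L, 9L)), z = 0))
  idx <- risk_index(tab)
  base <- baseline_rate(idx, beta = 0, alpha = 0)
  expect_equal(base$increments, 0.1)
  # shifting every alpha by log 2 halves every increment (the identified
  # quantity is the product)
  base2 <- baseline_rate(idx, beta = 0, alpha = log(2))
  expect_equal(base2$increments, base$increments / 2)
})

test_that("baseline matches a day-by-day brute-force scan", {
  pop <- small_population(21, n_facility = 3L, mean_size = 10)
  idx <- risk_index(pop$table)
  covs <- attr(pop$table, "covariates")
  beta <- rep(0.1, length(covs))
  alpha <- setNames(seq(-0.2, 0.2, length.out = idx$n_facility),
                    idx$facility_levels)
  base <- baseline_rate(idx, beta, alpha)
  orc <- oracle_baseline(as.data.frame(pop$table), covs, beta, alpha, idx$tau)
  expect_equal(base$event_times, orc$event_times)
  expect_equal(base$increments, orc$increments, tolerance = 1e-12)
})

test_that("expected counts re-sum identically in subject-major order", {
  pop <- small_population(33, n_facility = 4L, mean_size = 15)
  idx <- risk_index(pop$table)
  bfit <- fit_beta(idx)
  base <- baseline_rate(idx, bfit$beta, 0)
  ee <- expected_events(idx, base, bfit$beta)
  expect_equal(sum(ee$E_fac), sum(ee$E_subj), tolerance = 1e-12)
  # independent subject-major loop over the raw table
  df <- as.data.frame(pop$table)
  rd <- oracle_row_days(df)
  dmu <- numeric(idx$tau + 1L)
  dmu[base$event_times + 1L] <- base$increments
  w <- exp(drop(as.matrix(df[, idx$covariates]) %*% bfit$beta))
  e_slow <- vapply(unique(df$subject_id), function(s) {
    rows <- which(df$subject_id == s)
    sum(vapply(rows, function(r) w[r] * sum(dmu[(rd$lo[r]:rd$hi[r]) + 1L]),
               numeric(1L)))
  }, numeric(1L))
  expect_equal(unname(ee$E_subj[names(e_slow)]), unname(e_slow),
               tolerance = 1e-10)
  # a facility never at risk on event days has E = 0
  tab2 <- event_table(data.frame(
    subject_id = c("a", "b"), facility_id = c("f1", "f2"),
    start = c(0L, 20L), stop = c(5L, 30L), event = c(1L, 0L), z = 0))
  idx2 <- risk_index(tab2)
  base2 <- baseline_rate(idx2, 0, 0)
  expect_equal(unname(expected_events(idx2, base2, 0)$E_fac["f2"]), 0)
})

test_that("single-facility fixed point converges immediately to alpha 0, SHR 1", {
  pop <- small_population(3, n_facility = 1L, mean_size = 30)
  idx <- risk_index(pop$table)
  bfit <- fit_beta(idx)
  fe <- fit_alpha(idx, bfit$beta)
  expect_equal(unname(fe$alpha), 0, tolerance = 1e-12)
  expect_equal(unname(fe$shr), 1, tolerance = 1e-12)
  expect_true(fe$converged)
})

test_that("identical facilities share alpha 0 and SHR 1", {
  one <- data.frame(subject_id = sprintf("s%02d", 1:8), facility_id = "f1",
                    start = 0L, stop = rep(c(5L, 9L, 12L, 20L), 2L),
                    event = rep(c(1L, 1L, 0L, 1L), 2L),
                    z = rep(c(0.4, -0.1), each = 4L))
  clone <- one
  clone$subject_id <- sub("^s0", "t0", one$subject_id)
  clone$facility_id <- "f2"
  tab <- event_table(rbind(one, clone))
  idx <- risk_index(tab)
  bfit <- fit_beta(idx)
  fe <- fit_alpha(idx, bfit$beta)
  expect_equal(unname(fe$alpha), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(fe$shr), c(1, 1), tolerance = 1e-9)
})

test_that("fixed-point facility effects match a joint indicator-covariate partial-likelihood fit", {
  skip_if_not_installed("survival")
  for (seed in c(5, 17)) {
    pop <- small_population(seed, n_facility = 5L, mean_size = 25)
    fit <- shr_fit(pop$table)
    df <- coxph_frame(pop$table)
    covs <- attr(pop$table, "covariates")
    df$off <- drop(as.matrix(df[, covs]) %*% coef(fit))
    cx <- survival::coxph(
      survival::Surv(start2, stop, event) ~ factor(facility_id) + offset(off),
      data = df, ties = "breslow")
    a_ref <- fit$facility$alpha - fit$facility$alpha[1L]
    expect_equal(unname(a_ref[-1L]), unname(coef(cx)), tolerance = 2e-3)
  }
})

test_that("the alpha profile log-likelihood never decreases across iterations", {
  pop <- small_population(63, n_facility = 8L, mean_size = 20)
  idx <- risk_index(pop$table)
  bfit <- fit_beta(idx)
  fe <- fit_alpha(idx, bfit$beta)
  expect_true(all(diff(fe$loglik_history) >= -1e-8))
})

test_that("constraint, SHR identity and rescaling invariance hold on a converged fit", {
  pop <- small_population(44, n_facility = 7L, mean_size = 20)
  fit <- shr_fit(pop$table)
  fe <- fit$facility
  expect_true(fit$beta$converged && fe$converged)
  expect_lt(max(abs(fit$beta$score)), 1e-8)
  expect_equal(sum(fe$O_fac), sum(fe$E_fac), tolerance = 1e-8)
  expect_equal(tail(fe$C_history, 1L), 1, tolerance = 1e-6)
  on_ev <- fe$O_fac > 0
  expect_equal(unname(exp(fe$alpha[on_ev])),
               unname(fe$O_fac[on_ev] / fe$E_fac[on_ev]), tolerance = 1e-5)
  # rescaling: shift alpha by c and scale the baseline by e^c -> E and SHR
  # unchanged
  idx <- fit$index
  cshift <- 0.37
  base <- fit$baseline
  base$increments <- base$increments * exp(cshift)
  ee <- expected_events(idx, base, coef(fit))
  expect_equal(unname(ee$E_fac * exp(fe$alpha - cshift))[on_ev],
               unname(fe$E_fac * exp(fe$alpha))[on_ev], tolerance = 1e-10)
})

test_that("zero-event facilities get the sentinel and stay in the books", {
  df <- data.frame(
    subject_id = sprintf("s%02d", 1:9),
    facility_id = rep(c("f1", "f2", "f3"), each = 3L),
    start = 0L, stop = rep(c(10L, 20L, 30L), 3L),
    event = c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L),
    z = rep(c(0.2, -0.2, 0), 3L))
  tab <- event_table(df)
  idx <- risk_index(tab)
  fe <- fit_alpha(idx, 0)
  expect_equal(unname(fe$alpha["f3"]), -10)
  expect_true(fe$zero_event["f3"])
  expect_gt(fe$E_fac["f3"], 0)      # still accumulates expected events
  # the -10 sentinel (rather than -Inf) leaves a constraint gap of exactly
  # exp(-10) times the zero-event facilities' expected count
  gap <- sum(fe$O_fac) - sum(fe$E_fac)
  expect_lt(abs(gap - exp(-10) * sum(fe$E_fac[fe$zero_event])),
            1e-6 * sum(fe$E_fac))
})

test_that("non-finite beta and singular information are reported", {
  pop <- small_population(2, n_facility = 2L, mean_size = 8)
  idx <- risk_index(pop$table)
  expect_error(score_beta(idx, rep(NA_real_, idx$p)), "non-finite")
  df <- as.data.frame(pop$table)
  df$dup1 <- df$z1
  tab <- event_table(df[, c("subject_id", "facility_id", "start", "stop",
                            "event", "z1", "dup1")])
  expect_error(fit_beta(risk_index(tab)), "collinear.*dup1|dup1.*collinear")
})
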