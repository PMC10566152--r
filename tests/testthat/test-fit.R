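# Maximum-likelihood fitting across models and methods.

test_that("null data give near-zero slope estimates for every method", {
  s <- sim_cohort_outcomes(n = 400, beta0 = 1, beta1 = 0, seed = 8)
  for (m in c("am", "gm", "mgm", "adjusted")) {
    f <- fit_exposure_response(s$cohort$jem, s$cohort$histories, s$outcomes,
      model = "logistic", method = m
    )
    expect_true(glance(f)$converged)
    b1 <- tidy(f)$estimate[tidy(f)$term == "beta1"]
    se <- tidy(f)$std.error[tidy(f)$term == "beta1"]
    expect_lt(abs(b1), 4 * max(se, 0.05))
  }
})

test_that("degenerate JEM (SD -> 0) makes the adjusted fit match the AM fit", {
  co <- generate_cohort(cohort_config(n_subjects = 150), seed = 21)
  jem <- co$jem
  jem$sd <- jem$am / 400
  ex <- sample_exposures(co$histories, jem, 22)
  cm <- cumulative_exposure(ex)
  oc <- simulate_outcomes_nonstratified(cm, 1, 0.25, 23)
  # degree 60: the intercept alone drives series decay once SD vanishes
  fa <- fit_exposure_response(jem, co$histories, oc, "logistic", "adjusted",
    degree = 60
  )
  fm <- fit_exposure_response(jem, co$histories, oc, "logistic", "am")
  expect_equal(tidy(fa)$estimate, tidy(fm)$estimate, tolerance = 1e-3)
  # conditional model, same degeneracy
  s <- sim_cohort_outcomes(n = 150, beta1 = 0.2, seed = 31, stratified = TRUE)
  jem2 <- s$cohort$jem
  jem2$sd <- jem2$am / 400
  fca <- fit_exposure_response(jem2, s$cohort$histories, s$outcomes,
    "conditional-logistic", "adjusted"
  )
  fcm <- fit_exposure_response(jem2, s$cohort$histories, s$outcomes,
    "conditional-logistic", "am"
  )
  expect_equal(tidy(fca)$estimate, tidy(fcm)$estimate, tolerance = 1e-3)
})

test_that("mirrored strata give a zero conditional slope by symmetry", {
  oc <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4),
    stratum = c("a", "a", "b", "b"),
    case = c(1L, 0L, 1L, 0L),
    cummf = c(1, 2, 2, 1)
  )
  jem <- tibble::tibble(job_code = "J", am = 0.2, sd = 0.1)
  h <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4), job_code = "J",
    duration_years = c(5, 10, 10, 5)
  )
  f <- fit_exposure_response(jem, h, oc[, c("subject_id", "stratum", "case")],
    "conditional-logistic", "am"
  )
  expect_lt(abs(tidy(f)$estimate), 1e-4)
})

test_that("conditional surrogate fit reproduces survival::clogit", {
  s <- sim_cohort_outcomes(n = 250, beta1 = 0.25, seed = 12, stratified = TRUE)
  f <- fit_exposure_response(s$cohort$jem, s$cohort$histories, s$outcomes,
    "conditional-logistic", "am"
  )
  cm <- cumulative_exposure(
    s$cohort$histories, surrogate_levels(s$cohort$jem, "am")
  )
  df <- dplyr::inner_join(s$outcomes, cm, by = "subject_id")
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), case) ~ cummf + survival::strata(stratum),
    data = df, method = "exact"
  )
  expect_equal(tidy(f)$estimate, unname(coef(ref)), tolerance = 1e-4)
  expect_equal(tidy(f)$std.error, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-3)
})

test_that("likelihoods are invariant to rescaling durations against the slope", {
  s <- sim_cohort_outcomes(n = 40, beta1 = 0.2, seed = 14, stratified = TRUE)
  h2 <- s$cohort$histories
  h2$duration_years <- h2$duration_years * 2
  for (b1 in c(0.05, 0.15)) {
    expect_equal(
      adjusted_conditional_loglik(s$outcomes, s$cohort$histories, s$cohort$jem, b1),
      adjusted_conditional_loglik(s$outcomes, h2, s$cohort$jem, b1 / 2),
      tolerance = 1e-12
    )
    expect_equal(
      adjusted_logistic_prob(s$cohort$histories, s$cohort$jem, 0.7, b1)$prob,
      adjusted_logistic_prob(h2, s$cohort$jem, 0.7, b1 / 2)$prob,
      tolerance = 1e-12
    )
  }
})

test_that("analytic gradient of the adjusted logistic likelihood matches finite differences", {
  s <- sim_cohort_outcomes(n = 60, beta1 = 0.2, seed = 19)
  st <- berksonjem:::spell_table(s$cohort$histories, s$cohort$jem)
  ord <- s$outcomes$subject_id
  yy <- s$outcomes$case
  nll <- function(par) {
    p <- adjusted_logistic_prob(
      s$cohort$histories, s$cohort$jem, par[1], par[2],
      degree = 10
    )
    p <- p$prob[match(ord, p$subject_id)]
    -sum(yy * log(p) + (1 - yy) * log1p(-p))
  }
  set.seed(4)
  for (k in 1:20) {
    par <- c(runif(1, 0.2, 2), runif(1, 0.05, 0.35))
    ga <- berksonjem:::adjusted_logistic_nll_grad(st, par[1], par[2], 10, yy, ord)
    h <- 1e-5
    gn <- vapply(1:2, function(j) {
      e <- numeric(2)
      e[j] <- h
      (nll(par + e) - nll(par - e)) / (2 * h)
    }, 0)
    expect_equal(ga, gn, tolerance = 1e-5)
  }
})

test_that("profile log-likelihood peaks where fit() does", {
  s <- sim_cohort_outcomes(n = 200, beta1 = 0.2, seed = 25)
  f <- fit_exposure_response(s$cohort$jem, s$cohort$histories, s$outcomes,
    "logistic", "am"
  )
  b1_hat <- tidy(f)$estimate[tidy(f)$term == "beta1"]
  grid <- seq(max(0, b1_hat - 0.3), b1_hat + 0.3, length.out = 21)
  prof <- profile_loglik(s$cohort$jem, s$cohort$histories, s$outcomes,
    "logistic", "am",
    beta1_grid = grid
  )
  expect_lt(abs(grid[which.max(prof$loglik)] - b1_hat), diff(grid)[1] + 1e-9)
  # adjusted and AM profiles agree everywhere in the small-error limit
  jem_tight <- s$cohort$jem
  jem_tight$sd <- jem_tight$am / 100
  grid2 <- seq(0.05, 0.3, length.out = 6)
  pa <- profile_loglik(jem_tight, s$cohort$histories, s$outcomes,
    "logistic", "adjusted",
    beta1_grid = grid2, degree = 40
  )
  pm <- profile_loglik(jem_tight, s$cohort$histories, s$outcomes,
    "logistic", "am",
    beta1_grid = grid2
  )
  expect_lt(max(abs(pa$loglik - pm$loglik)), 1e-3)
})

test_that("design errors are raised for inconsistent model inputs", {
  s <- sim_cohort_outcomes(n = 30, beta1 = 0.1, seed = 33)
  oc_extra <- dplyr::bind_rows(
    s$outcomes,
    tibble::tibble(subject_id = "GHOST", case = 1L)
  )
  expect_error(
    fit_exposure_response(s$cohort$jem, s$cohort$histories, oc_extra, "logistic", "am"),
    regexp = "GHOST", class = "bjem_error_design"
  )
  expect_error(
    fit_exposure_response(
      s$cohort$jem, s$cohort$histories, s$outcomes,
      "conditional-logistic", "am"
    ),
    class = "bjem_error_design"
  )
})
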