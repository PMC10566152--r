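# Series kernels against closed forms and the quadrature oracle.
#
# Frozen reference values were computed with the quadrature oracle
# (stats::integrate at rel.tol 1e-12) on the defining integrals.

test_that("zero slope collapses the adjusted logistic probability exactly", {
  for (b0 in c(0, 0.5, 1, 2)) {
    p <- adjusted_logistic_prob(two_spells(), toy_jem(), b0, 0)
    expect_identical(p$prob, plogis(b0))
  }
})

test_that("series matches the marginal-likelihood integral once converged", {
  # single spell, shape 1: integral of plogis(1 + 2x) Gamma(x; 1, 6.667)
  frozen <- 0.781691641497
  p40 <- adjusted_logistic_prob(one_spell(t = 10), toy_jem(), 1, 0.2, degree = 40)
  expect_equal(p40$prob, frozen, tolerance = 1e-9)
  orc <- quadrature_oracle("logistic-prob", one_spell(t = 10), toy_jem(),
    beta0 = 1, beta1 = 0.2
  )
  expect_equal(orc, frozen, tolerance = 1e-9)
  # truncated series sits within its own alternating-tail bound of the oracle
  p10 <- adjusted_logistic_prob(one_spell(t = 10), toy_jem(), 1, 0.2,
    degree = 10, tail_check = TRUE
  )
  expect_lte(abs(p10$prob - orc), p10$tail_bound + 1e-12)
})

test_that("alternating-tail bound covers the truncation error across random draws", {
  set.seed(2091)
  for (k in 1:200) {
    b0 <- runif(1, 0, 2)
    b1 <- runif(1, 0.005, 0.4)
    t1 <- runif(1, 1, 10)
    jem <- tibble::tibble(
      job_code = "Z", am = runif(1, 0.1, 0.5),
      sd = runif(1, 0.05, 0.4), gm = 0.1, gsd = 2
    )
    h <- tibble::tibble(subject_id = "S1", job_code = "Z", duration_years = t1)
    trunc <- adjusted_logistic_prob(h, jem, b0, b1, degree = 10, tail_check = TRUE)
    conv <- adjusted_logistic_prob(h, jem, b0, b1, degree = 400)
    expect_lte(abs(trunc$prob - conv$prob), trunc$tail_bound + 1e-10)
  }
})

test_that("converged series agrees with adaptive quadrature to 1e-8", {
  set.seed(515)
  for (k in 1:30) {
    b0 <- runif(1, 0, 2)
    b1 <- runif(1, 0.01, 0.4)
    jem <- tibble::tibble(
      job_code = c("A", "B"), am = runif(2, 0.1, 0.5),
      sd = runif(2, 0.05, 0.4), gm = 0.1, gsd = 2
    )
    n_sp <- sample(1:2, 1)
    h <- tibble::tibble(
      subject_id = "S1", job_code = c("A", "B")[seq_len(n_sp)],
      duration_years = runif(n_sp, 1, 10)
    )
    ser <- adjusted_logistic_prob(h, jem, b0, b1, degree = 500)$prob
    orc <- quadrature_oracle("logistic-prob", h, jem, beta0 = b0, beta1 = b1)
    expect_equal(ser, orc, tolerance = 1e-8)
  }
})

test_that("adjusted logistic probability is monotone in slope and durations", {
  grid <- seq(0.01, 0.4, length.out = 12)
  p <- vapply(
    grid,
    function(b1) adjusted_logistic_prob(two_spells(), toy_jem(), 0.5, b1)$prob,
    0
  )
  expect_true(all(diff(p) > 0))
  t_grid <- seq(1, 25, length.out = 10)
  p_t <- vapply(
    t_grid,
    function(t) adjusted_logistic_prob(one_spell(t = t), toy_jem(), 0.5, 0.2)$prob,
    0
  )
  expect_true(all(diff(p_t) > 0))
})

test_that("series domain errors route negative parameters to the oracle", {
  expect_error(
    adjusted_logistic_prob(one_spell(), toy_jem(), -0.1, 0.2),
    class = "bjem_error_series_domain"
  )
  expect_error(
    adjusted_poisson_logpmf(0, one_spell(), toy_jem(), 1, -0.2),
    class = "bjem_error_series_domain"
  )
  # the oracle itself covers the whole real parameter space
  v <- quadrature_oracle("logistic-prob", one_spell(), toy_jem(),
    beta0 = -1, beta1 = -0.3
  )
  expect_gt(v, 0)
  expect_lt(v, 1)
})

test_that("AM plug-in probability is the small-error limit", {
  # closed form
  p <- am_logistic_prob(one_spell(t = 10), toy_jem(), 1, 0.2)
  expect_equal(p$prob, plogis(1 + 0.2 * 10 * 0.15))
  jem0 <- toy_jem()
  jem0$am <- 0
  jem0$am <- c(1e-12, 1e-12, 1e-12) # logistic(0) limit at vanishing exposure
  expect_equal(am_logistic_prob(one_spell(), jem0, 0, 5)$prob, 0.5, tolerance = 1e-9)
  # AM/SD = 100: adjusted and plug-in agree to 1e-4
  jem_tight <- toy_jem()
  jem_tight$sd <- jem_tight$am / 100
  pa <- adjusted_logistic_prob(two_spells(), jem_tight, 1, 0.3, degree = 50)
  pm <- am_logistic_prob(two_spells(), jem_tight, 1, 0.3)
  expect_lt(abs(pa$prob - pm$prob), 1e-4)
})

test_that("adjusted Poisson pmf matches closed forms and the oracle", {
  # beta1 = 0: plain Poisson with rate e^beta0; P(Y=0) = exp(-e)
  lp <- adjusted_poisson_logpmf(0, one_spell(), toy_jem(), 1, 0)
  expect_equal(lp$log_pmf, -exp(1), tolerance = 1e-14)
  # frozen quadrature of E[exp(-e^{0.05 x})] under Gamma(1, 1)
  jem11 <- tibble::tibble(job_code = "U", am = 1, sd = 1, gm = 0.6, gsd = 2)
  h1 <- tibble::tibble(subject_id = "S1", job_code = "U", duration_years = 1)
  frozen <- 0.349533469965
  lp2 <- adjusted_poisson_logpmf(0, h1, jem11, 0, 0.05, degree = 15)
  expect_equal(exp(lp2$log_pmf), frozen, tolerance = 1e-9)
  expect_equal(
    quadrature_oracle("poisson-pmf", h1, jem11, beta0 = 0, beta1 = 0.05, y = 0),
    frozen,
    tolerance = 1e-9
  )
})

test_that("Poisson validity constraint errors and caps as specified", {
  # beta1 * t >= AM/SD^2 already at n + y = 1 -> undefined marginal
  jem11 <- tibble::tibble(job_code = "U", am = 1, sd = 1, gm = 0.6, gsd = 2)
  h1 <- tibble::tibble(subject_id = "S1", job_code = "U", duration_years = 1)
  expect_error(
    adjusted_poisson_logpmf(1, h1, jem11, 0, 1.2),
    class = "bjem_error_adjustment_undefined"
  )
  # y = 0 survives but the requested degree is capped, with a warning
  expect_warning(
    lp <- adjusted_poisson_logpmf(0, h1, jem11, 0, 0.3, degree = 10),
    regexp = "capped"
  )
  expect_lt(lp$degree_used, 10)
})

test_that("marginal mean response has the product-of-MGFs closed form", {
  expect_equal(adjusted_mean_response(two_spells(), toy_jem(), 0)$mean_response, 1)
  # shape-1 spell: geometric MGF (1 - b1 t sd^2/am)^-1
  mr <- adjusted_mean_response(one_spell(t = 2), toy_jem(), 0.5)
  expect_equal(mr$mean_response, 1 / (1 - 0.5 * 2 * 0.15), tolerance = 1e-12)
  expect_equal(
    mr$mean_response,
    quadrature_oracle("mean-response", one_spell(t = 2), toy_jem(), beta1 = 0.5),
    tolerance = 1e-8
  )
  # Jensen: marginal mean dominates the AM plug-in rate
  set.seed(77)
  for (k in 1:25) {
    b1 <- runif(1, 0.01, 0.3)
    mr <- adjusted_mean_response(two_spells(), toy_jem(), b1)$mean_response
    am_rate <- exp(b1 * cumulative_exposure(
      two_spells(), surrogate_levels(toy_jem(), "am")
    )$cummf)
    expect_gte(mr, am_rate)
  }
  expect_error(
    adjusted_mean_response(one_spell(t = 10), toy_jem(), 0.9),
    regexp = "S1/J1", class = "bjem_error_adjustment_undefined"
  )
})

test_that("gamma MGF and the generic MGF plug-in reproduce the gamma forms", {
  expect_equal(mgf_gamma(0, 3, 2), 1)
  expect_equal(mgf_gamma(-1, 1, 1), 0.5)
  expect_error(mgf_gamma(2, 1, 1), class = "bjem_error_domain")
  params <- jem_gamma_params(toy_jem())
  gamma_mgf <- function(t, job) {
    row <- params[params$job_code == job, ]
    mgf_gamma(t, row$shape, row$rate)
  }
  p_plug <- adjusted_logistic_prob(two_spells(), toy_jem(), 1, 0.2, mgf = gamma_mgf)
  p_closed <- adjusted_logistic_prob(two_spells(), toy_jem(), 1, 0.2)
  expect_equal(p_plug$prob, p_closed$prob, tolerance = 1e-12)
  m_plug <- adjusted_mean_response(two_spells(), toy_jem(), 0.2, mgf = gamma_mgf)
  m_closed <- adjusted_mean_response(two_spells(), toy_jem(), 0.2)
  expect_equal(m_plug$mean_response, m_closed$mean_response, tolerance = 1e-12)
})

test_that("conditional likelihood is the SoftMax over stratum scores", {
  d <- toy_strata()
  # beta1 = 0: every subject equally likely -> prod 1/(N_k + 1)
  expect_equal(conditional_logistic_loglik(d, 0), log(1 / 3) + log(1 / 3))
  # case exposure equal to all controls: symmetry for any slope
  d_sym <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4), stratum = "a",
    case = c(1L, 0L, 0L, 0L), cummf = 2
  )
  for (b1 in c(0, 0.4, 3)) {
    expect_equal(conditional_logistic_loglik(d_sym, b1), log(1 / 4))
  }
  # equals the binomial conditioning of independent Poisson responses
  lam <- exp(0.3 * d$cummf[d$stratum == "a"])
  expect_equal(
    exp(conditional_logistic_loglik(dplyr::filter(d, stratum == "a"), 0.3)),
    lam[1] / sum(lam)
  )
  # SoftMax normalisation within strata
  probs <- stratum_case_probs(dplyr::mutate(d, score = 0.25 * cummf))
  sums <- tapply(probs$prob, probs$stratum, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})

test_that("adjusted conditional likelihood uses marginal-mean weights", {
  jem <- toy_jem()
  h <- dplyr::bind_rows(lapply(sprintf("S%d", 1:4), function(id) {
    tibble::tibble(
      subject_id = id, job_code = c("J1", "J2"),
      duration_years = c(2, 3)
    )
  }))
  oc <- tibble::tibble(
    subject_id = sprintf("S%d", 1:4), stratum = "a",
    case = c(1L, 0L, 0L, 0L)
  )
  # identical histories: symmetry gives 1/(N_k+1) at any valid slope
  for (b1 in c(0, 0.2, 0.5)) {
    expect_equal(adjusted_conditional_loglik(oc, h, jem, b1), log(1 / 4))
  }
  # beta1 = 0 with arbitrary histories: all weights are 1
  s <- sim_cohort_outcomes(n = 60, beta1 = 0.2, seed = 11, stratified = TRUE)
  n_k <- table(s$outcomes$stratum)
  expect_equal(
    adjusted_conditional_loglik(s$outcomes, s$cohort$histories, s$cohort$jem, 0),
    sum(log(1 / n_k))
  )
  # per-subject weights equal the quadrature of E[exp(b1 sum t X)]
  w <- adjusted_log_weights(h[h$subject_id == "S1", ], jem, 0.3)
  expect_equal(
    exp(w$score),
    quadrature_oracle("mean-response", h[h$subject_id == "S1", ], jem, beta1 = 0.3),
    tolerance = 1e-8
  )
  # validity violation is a classed error
  expect_error(
    adjusted_conditional_loglik(oc, h, jem, 4),
    class = "bjem_error_adjustment_undefined"
  )
  # design errors: zero or two cases in a stratum
  oc_bad <- oc
  oc_bad$case <- c(1L, 1L, 0L, 0L)
  expect_error(
    adjusted_conditional_loglik(oc_bad, h, jem, 0.1),
    class = "bjem_error_design"
  )
})

test_that("scaling all SDs towards zero drives adjusted forms to AM forms", {
  h <- two_spells()
  errs <- vapply(c(1, 0.1, 0.01), function(eps) {
    jem_eps <- toy_jem()
    jem_eps$sd <- jem_eps$sd * eps
    max(
      abs(
        adjusted_logistic_prob(h, jem_eps, 1, 0.25, degree = 50)$prob -
          am_logistic_prob(h, jem_eps, 1, 0.25)$prob
      )
    )
  }, 0)
  expect_true(all(diff(errs) < 0))
})
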