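# Berkson-adjusted likelihood kernels under the gamma exposure model.
#
# The marginal ("Berkson-adjusted") likelihood integrates the outcome model
# over each spell's gamma exposure distribution. Under the gamma model every
# integral reduces to gamma moment generating function (MGF) evaluations:
#   M_X(t) = (1 - t / lambda)^(-r),  t < lambda,
# with r = AM^2/SD^2 and lambda = AM/SD^2 from the JEM. The adjusted logistic
# response probability expands as the alternating series
#   p_i = sum_{n>=0} (-1)^n exp(-n b0) prod_j (1 + n b1 t_ij SD_j^2/AM_j)^(-r_j),
# valid for b0 >= 0, b1 > 0; the Poisson pmf has an analogous series with an
# extra 1/n! and a validity constraint (n + y) b1 t_ij < AM_j/SD_j^2 on every
# retained term. Truncation keeps terms n = 0..degree (degree + 1 terms); for
# an alternating series with decreasing terms the absolute truncation error is
# bounded by the first omitted term, which `tail_check = TRUE` reports.

#' Gamma moment generating function
#'
#' `M_X(t) = (1 - t/rate)^(-shape)` for `t < rate`. Vectorised over all
#' arguments.
#'
#' @param t evaluation point(s); must satisfy `t < rate`.
#' @param shape,rate gamma parameters (e.g. from [jem_gamma_params()]).
#' @return numeric vector of MGF values.
#' @export
mgf_gamma <- function(t, shape, rate) {
  if (any(t >= rate)) {
    bjem_abort(
      "mgf_gamma() requires t < rate (the gamma MGF does not exist at or beyond its rate).",
      "domain"
    )
  }
  exp(-shape * log1p(-t / rate))
}

#' @noRd
check_series_domain <- function(beta0, beta1) {
  if (beta0 < 0 || beta1 < 0) {
    bjem_abort(
      paste0(
        "The alternating series requires beta0 >= 0 and beta1 >= 0 ",
        "(beta1 = 0 is handled in closed form); for other parameters use ",
        "quadrature_oracle()."
      ),
      "series_domain"
    )
  }
}

# Per-subject log series factors: N x (degree+2) matrix of
# log G_{i,n} = sum_j shape_j * log1p(n * beta1 * t_ij * sd_j^2 / am_j),
# for n = 0..degree+1 (the extra column feeds the tail bound).
#' @noRd
series_log_factors <- function(st, beta1, degree) {
  n_subj <- length(attr(st, "subjects"))
  nn <- 0:(degree + 1)
  lg <- outer(beta1 * st$tc, nn, function(x, n) log1p(n * x))
  lw <- st$shape * lg
  out <- rowsum(lw, st$idx, reorder = TRUE)
  stopifnot(nrow(out) == n_subj)
  out
}

#' Berkson-adjusted logistic response probability
#'
#' Evaluates, for each subject, the marginal probability of being a case under
#' logistic regression on cumulative exposure when each spell's exposure is
#' integrated over its gamma distribution. Computed with the alternating
#' series truncated at `degree` (terms `n = 0..degree`); `beta1 = 0` collapses
#' analytically to `plogis(beta0)`. Values are clipped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' A generic exposure model can be supplied through `mgf`: a function
#' `mgf(t, job_code)` returning that occupation's MGF at `t`; the series then
#' uses `prod_j mgf(-n * beta1 * t_ij, job_code_j)` in place of the gamma
#' closed form.
#'
#' @param histories job-history tibble (`subject_id`, `job_code`,
#'   `duration_years`).
#' @param jem JEM tibble; see [validate_jem()].
#' @param beta0 intercept, must be `>= 0` for the series.
#' @param beta1 slope per microtesla-year, must be `>= 0` for the series.
#' @param degree series truncation degree M (retains terms `n = 0..M`);
#'   default 10.
#' @param tail_check if `TRUE`, also return the magnitude of the first
#'   omitted term as `tail_bound` (a rigorous error bound whenever successive
#'   terms decrease in magnitude).
#' @param mgf optional function `(t, job_code) -> M_X(t)` replacing the gamma
#'   MGF.
#' @return tibble `subject_id`, `prob` (and `tail_bound` if requested).
#' @export
adjusted_logistic_prob <- function(histories, jem, beta0, beta1,
                                   degree = 10, tail_check = FALSE,
                                   mgf = NULL) {
  check_series_domain(beta0, beta1)
  st <- spell_table(histories, jem)
  subjects <- attr(st, "subjects")
  if (beta1 == 0) {
    out <- tibble(subject_id = subjects, prob = rep(plogis(beta0), length(subjects)))
    if (tail_check) out$tail_bound <- 0
    return(out)
  }
  nn <- 0:(degree + 1)
  if (is.null(mgf)) {
    lf <- series_log_factors(st, beta1, degree)
  } else {
    # generic MGF plug-in: log factor = -sum_j log M_X(-n b1 t_ij)
    lm <- matrix(0, nrow = nrow(st), ncol = length(nn))
    for (k in seq_along(nn)) {
      lm[, k] <- -log(vapply(
        seq_len(nrow(st)),
        function(s) mgf(-nn[k] * beta1 * st$duration_years[s], st$job_code[s]),
        0
      ))
    }
    lf <- rowsum(lm, st$idx, reorder = TRUE)
  }
  log_terms <- -outer(rep(beta0, nrow(lf)), nn, `*`) - lf
  signs <- rep_len(c(1, -1), degree + 1)
  p <- drop(exp(log_terms[, seq_len(degree + 1), drop = FALSE]) %*% signs)
  out <- tibble(subject_id = subjects, prob = unname(clip_prob(p)))
  if (tail_check) out$tail_bound <- unname(exp(log_terms[, degree + 2]))
  out
}

#' Arithmetic-mean surrogate logistic probability
#'
#' The small-error limit of [adjusted_logistic_prob()]: as `SD_j/AM_j -> 0`
#' the adjusted probability converges to the ordinary logistic probability
#' evaluated at the AM-surrogate cumulative exposure,
#' `plogis(beta0 + beta1 * sum_j t_ij AM_j)`.
#'
#' @inheritParams adjusted_logistic_prob
#' @return tibble `subject_id`, `prob`.
#' @export
am_logistic_prob <- function(histories, jem, beta0, beta1) {
  cummf <- cumulative_exposure(histories, surrogate_levels(jem, "am"))
  tibble(
    subject_id = cummf$subject_id,
    prob = plogis(beta0 + beta1 * cummf$cummf)
  )
}

#' Berkson-adjusted marginal mean of a Poisson response
#'
#' The marginal mean `E[Y_i | beta1]` of a Poisson response with log-linear
#' rate in cumulative exposure, integrated over the gamma exposure model:
#' `prod_j (1 - beta1 t_ij SD_j^2/AM_j)^(-AM_j^2/SD_j^2)` — a product of gamma
#' MGFs, exact (no truncation). Exists only under the validity constraint
#' `beta1 * t_ij < AM_j/SD_j^2` for every spell.
#'
#' @inheritParams adjusted_logistic_prob
#' @param mgf optional function `(t, job_code)`; the marginal mean becomes
#'   `prod_j mgf(beta1 * t_ij, job_code_j)`.
#' @return tibble `subject_id`, `mean_response`.
#' @export
adjusted_mean_response <- function(histories, jem, beta1, mgf = NULL) {
  st <- spell_table(histories, jem)
  subjects <- attr(st, "subjects")
  if (!is.null(mgf)) {
    v <- vapply(
      seq_len(nrow(st)),
      function(s) log(mgf(beta1 * st$duration_years[s], st$job_code[s])),
      0
    )
    lmean <- rowsum(v, st$idx, reorder = TRUE)[, 1]
    return(tibble(subject_id = subjects, mean_response = unname(exp(lmean))))
  }
  bad <- which(beta1 * st$tc >= 1)
  if (length(bad) > 0) {
    bjem_abort(
      paste0(
        "Marginal mean does not exist: beta1 * t >= AM/SD^2 for spell(s) ",
        paste0(
          st$subject_id[bad], "/", st$job_code[bad],
          collapse = ", "
        )
      ),
      "adjustment_undefined"
    )
  }
  lmean <- rowsum(-st$shape * log1p(-beta1 * st$tc), st$idx, reorder = TRUE)[, 1]
  tibble(subject_id = subjects, mean_response = unname(exp(lmean)))
}

#' Berkson-adjusted Poisson log-probability
#'
#' Log of the marginal Poisson pmf `P(Y_i = y_i)` under the gamma exposure
#' model, via the alternating series with terms
#' `(-1)^n / n! * exp((n + y) beta0) * prod_j (1 - (n + y) beta1 t_ij SD_j^2/AM_j)^(-r_j)`.
#' A term exists only while `(n + y) beta1 t_ij < AM_j/SD_j^2` for all spells;
#' the effective truncation is the smaller of `degree` and the largest valid
#' `n`, with a warning when validity caps the requested degree. If even the
#' `n = 0` term is undefined (possible when `y >= 1`) the marginal pmf cannot
#' be series-evaluated and an error of class
#' `bjem_error_adjustment_undefined` is raised.
#'
#' @inheritParams adjusted_logistic_prob
#' @param y non-negative integer response(s): a single value recycled to all
#'   subjects or one per subject (in first-seen subject order).
#' @return tibble `subject_id`, `y`, `log_pmf`, `degree_used`, `capped`, and
#'   `tail_ok` (`FALSE` when the retained terms had not yet entered their
#'   decaying regime, i.e. the truncated value should not be trusted).
#' @export
adjusted_poisson_logpmf <- function(y, histories, jem, beta0, beta1, degree = 10) {
  check_series_domain(beta0, beta1)
  st <- spell_table(histories, jem)
  subjects <- attr(st, "subjects")
  n_subj <- length(subjects)
  if (any(y < 0 | y != round(y))) {
    bjem_abort("`y` must hold non-negative integers.", "invalid_input")
  }
  y <- rep_len(as.numeric(y), n_subj)
  if (beta1 == 0) {
    lam <- exp(beta0)
    return(tibble(
      subject_id = subjects, y = y,
      log_pmf = dpois(y, lam, log = TRUE),
      degree_used = rep(degree, n_subj), capped = FALSE, tail_ok = TRUE
    ))
  }
  # per-subject strictest validity margin: (n + y) * beta1 * max_j(tc) < 1
  max_tc <- unname(vapply(split(st$tc, st$idx), max, 0)[as.character(seq_len(n_subj))])
  m_lim <- 1 / (beta1 * max_tc) # need n + y < m_lim
  n_max <- ceiling(m_lim - y) - 1
  n_max[m_lim - y == floor(m_lim - y)] <- (m_lim - y - 1)[m_lim - y == floor(m_lim - y)]
  if (any(n_max < 0)) {
    bad <- which(n_max < 0)
    bjem_abort(
      paste0(
        "Adjusted Poisson pmf undefined (y * beta1 * t >= AM/SD^2 already at n = 0) ",
        "for subject(s): ", paste(subjects[bad], collapse = ", ")
      ),
      "adjustment_undefined"
    )
  }
  degree_used <- pmin(degree, n_max)
  capped <- degree_used < degree
  if (any(capped)) {
    warn(paste0(
      "Validity constraint capped the Poisson series degree below ", degree,
      " for ", sum(capped), " subject(s)."
    ))
  }
  log_pmf <- numeric(n_subj)
  tail_ok <- logical(n_subj)
  spl <- split(seq_len(nrow(st)), st$idx)
  for (i in seq_len(n_subj)) {
    rows <- spl[[as.character(i)]]
    nn <- 0:degree_used[i]
    # log |term_n| = -lfactorial(n) + (n+y) b0 - sum_j r_j log(1 - (n+y) b1 tc_j)
    lt <- vapply(nn, function(n) {
      -lfactorial(n) + (n + y[i]) * beta0 -
        sum(st$shape[rows] * log1p(-(n + y[i]) * beta1 * st$tc[rows]))
    }, 0)
    q <- signed_exp_sum(lt, rep_len(c(1, -1), length(nn)))
    q <- max(q, 1e-300) # guard: partial alternating sum can dip non-positive
    log_pmf[i] <- log(q) - lfactorial(y[i])
    # the truncated value is trustworthy only when the retained terms have
    # entered their decaying regime and the last one is negligible against q
    tail_ok[i] <- length(lt) >= 2 &&
      lt[length(lt)] < lt[length(lt) - 1] &&
      lt[length(lt)] - log(q) < log(1e-6)
  }
  tibble(
    subject_id = subjects, y = y, log_pmf = log_pmf,
    degree_used = degree_used, capped = capped, tail_ok = tail_ok
  )
}

# ---- conditional logistic ---------------------------------------------------

#' @noRd
validate_strata <- function(data) {
  data <- as_tibble(data)
  required <- c("subject_id", "stratum", "case")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    bjem_abort(
      paste0("Stratified data missing column(s): ", paste(missing_cols, collapse = ", ")),
      "design"
    )
  }
  counts <- tapply(data$case, data$stratum, sum)
  bad <- names(counts)[counts != 1]
  if (length(bad) > 0) {
    bjem_abort(
      paste0(
        "Each stratum must contain exactly one case; violated by stratum/strata: ",
        paste(bad, collapse = ", ")
      ),
      "design"
    )
  }
  sizes <- table(data$stratum)
  if (any(sizes < 2)) {
    bjem_abort("Each stratum needs at least one control.", "design")
  }
  data
}

#' Per-subject case probabilities within matched strata
#'
#' The conditional-logistic (SoftMax) probability that each subject is the
#' stratum's case, given per-subject linear scores `s_u`:
#' `exp(s_u) / sum_{v in stratum} exp(s_v)`, computed with max-subtraction for
#' stability. Probabilities sum to one within each stratum.
#'
#' @param data tibble with columns `subject_id`, `stratum`, and `score`.
#' @return `data` with a `prob` column appended.
#' @export
stratum_case_probs <- function(data) {
  data <- as_tibble(data)
  if (!all(c("subject_id", "stratum", "score") %in% names(data))) {
    bjem_abort("`data` must have columns subject_id, stratum, score.", "design")
  }
  data %>%
    group_by(.data$stratum) %>%
    mutate(prob = {
      m <- max(.data$score)
      e <- exp(.data$score - m)
      e / sum(e)
    }) %>%
    ungroup()
}

#' Conditional logistic log-likelihood on cumulative exposure
#'
#' The matched case-control likelihood: over strata `k` holding one case and
#' `N_k` controls, the product of SoftMax probabilities that the observed case
#' has the largest outcome, with per-subject score `beta1 * cummf`. Equivalent
#' to conditioning independent Poisson responses with log-linear rates on a
#' stratum total of one. Returned on the log scale.
#'
#' @param data tibble with `subject_id`, `stratum`, `case` (0/1, exactly one
#'   case per stratum) and `cummf` (cumulative exposure, microtesla-years).
#' @param beta1 slope per microtesla-year (any real value).
#' @return scalar log-likelihood (`<= 0`).
#' @export
conditional_logistic_loglik <- function(data, beta1) {
  data <- validate_strata(data)
  if (!("cummf" %in% names(data))) {
    bjem_abort("`data` must carry a cummf column.", "design")
  }
  scored <- stratum_case_probs(data %>% mutate(score = beta1 * .data$cummf))
  sum(log(clip_prob(scored$prob[scored$case == 1])))
}

#' Berkson-adjusted conditional logistic log-likelihood
#'
#' Replaces each subject's SoftMax weight `exp(beta1 * cummf_u)` by the
#' marginal Poisson mean under the gamma exposure model,
#' `A_u = prod_j (1 - beta1 t_uj SD_j^2/AM_j)^(-r_j)` (see
#' [adjusted_mean_response()]), conditioning the independent adjusted Poisson
#' responses on one case per stratum. Requires the validity constraint
#' `beta1 * t_uj < AM_j/SD_j^2` for every spell of every subject.
#'
#' @param outcomes tibble `subject_id`, `stratum`, `case` (one case per
#'   stratum).
#' @param histories job-history tibble covering every subject in `outcomes`.
#' @param jem JEM tibble.
#' @param beta1 slope, `beta1 >= 0` within the validity region.
#' @return scalar log-likelihood.
#' @export
adjusted_conditional_loglik <- function(outcomes, histories, jem, beta1) {
  outcomes <- validate_strata(outcomes)
  scores <- adjusted_log_weights(histories, jem, beta1)
  data <- outcomes %>% inner_join(scores, by = "subject_id")
  if (nrow(data) != nrow(outcomes)) {
    bjem_abort("Some subjects in `outcomes` have no job history.", "design")
  }
  scored <- stratum_case_probs(data)
  sum(log(clip_prob(scored$prob[scored$case == 1])))
}

#' Log SoftMax weights of the adjusted conditional likelihood
#'
#' `log A_u = -sum_j r_j log(1 - beta1 t_uj SD_j^2/AM_j)`, one row per
#' subject. Exposed separately so the weights can be validated against
#' quadrature of `E[exp(beta1 sum_j t_uj X_uj)]`.
#'
#' @inheritParams adjusted_conditional_loglik
#' @return tibble `subject_id`, `score`.
#' @export
adjusted_log_weights <- function(histories, jem, beta1) {
  st <- spell_table(histories, jem)
  subjects <- attr(st, "subjects")
  bad <- which(beta1 * st$tc >= 1)
  if (length(bad) > 0) {
    bjem_abort(
      paste0(
        "Validity constraint beta1 * t < AM/SD^2 violated for spell(s): ",
        paste0(st$subject_id[bad], "/", st$job_code[bad], collapse = ", ")
      ),
      "adjustment_undefined"
    )
  }
  score <- rowsum(-st$shape * log1p(-beta1 * st$tc), st$idx, reorder = TRUE)[, 1]
  tibble(subject_id = subjects, score = unname(score))
}
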