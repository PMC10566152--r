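# Maximum-likelihood fitting of the exposure-response slope under each
# (model, method) combination.
#
# Surrogate methods plug a deterministic per-occupation level (AM, GM, or
# MGM) into the standard likelihood: ordinary logistic and Poisson surrogate
# fits go through stats::glm; the conditional-logistic surrogate maximises
# the matched SoftMax likelihood implemented here. Adjusted methods maximise
# the Berkson-adjusted likelihoods, with box constraints keeping the search
# inside the series/validity domain: beta0 >= 0 for the adjusted logistic and
# Poisson fits, and beta1 below the validity bound
# min_{spells} AM_j / (SD_j^2 * t_ij), shrunk by a relative margin of 1e-6
# because the adjusted conditional/Poisson likelihoods blow up at the
# boundary. The surrogate-AM fit seeds the adjusted fit.

BJEM_MODELS <- c("logistic", "poisson", "conditional-logistic")
BJEM_METHODS <- c("adjusted", "am", "gm", "mgm")

#' Fit an exposure-response slope from JEM-based histories
#'
#' @param jem JEM tibble (see [validate_jem()]).
#' @param histories job-history tibble (`subject_id`, `job_code`,
#'   `duration_years`).
#' @param outcomes tibble `subject_id`, `case` (0/1 for logistic models, a
#'   count for `model = "poisson"`), plus `stratum` when
#'   `model = "conditional-logistic"`.
#' @param model outcome model: `"logistic"`, `"poisson"`, or
#'   `"conditional-logistic"` (fits `beta1` only; the intercept cancels).
#' @param method `"adjusted"` (Berkson-adjusted likelihood) or a surrogate
#'   plug-in `"am"`, `"gm"`, `"mgm"`.
#' @param degree series truncation degree for the adjusted logistic/Poisson
#'   likelihoods.
#' @param control optional list: `maxit` (default 200), `factr`-style
#'   tolerance `reltol` (default 1e-10), `beta1_upper` to override the
#'   validity-derived upper bound.
#' @return an object of class `berkson_fit`; see [tidy.berkson_fit()] and
#'   [glance.berkson_fit()].
#' @export
fit_exposure_response <- function(jem, histories, outcomes,
                                  model = BJEM_MODELS,
                                  method = BJEM_METHODS,
                                  degree = 10,
                                  control = list()) {
  model <- arg_match(model, BJEM_MODELS)
  method <- arg_match(method, BJEM_METHODS)
  jem <- validate_jem(jem)
  histories <- validate_histories(histories)
  outcomes <- as_tibble(outcomes)
  if (!all(c("subject_id", "case") %in% names(outcomes))) {
    bjem_abort("`outcomes` must have columns subject_id and case.", "design")
  }
  outcomes$subject_id <- as.character(outcomes$subject_id)
  missing_hist <- setdiff(outcomes$subject_id, histories$subject_id)
  if (length(missing_hist) > 0) {
    bjem_abort(
      paste0(
        "Subject id(s) in outcomes without job histories: ",
        paste(head(missing_hist, 10), collapse = ", ")
      ),
      "design"
    )
  }
  histories <- histories %>% filter(.data$subject_id %in% outcomes$subject_id)
  if (model == "conditional-logistic") {
    fit_conditional(jem, histories, outcomes, method, control)
  } else {
    fit_unconditional(jem, histories, outcomes, model, method, degree, control)
  }
}

#' @noRd
fit_control <- function(control) {
  modifyList(list(maxit = 200L, reltol = 1e-10, beta1_upper = NULL), control)
}

# validity-derived upper box for beta1 in adjusted Poisson / conditional fits
#' @noRd
validity_upper <- function(jem, histories, y = NULL) {
  st <- spell_table(histories, jem)
  mult <- 1
  if (!is.null(y)) {
    ymap <- setNames(pmax(y, 1), names(y))
    mult <- ymap[st$subject_id]
  }
  min(1 / (st$tc * mult))
}

#' @noRd
fit_unconditional <- function(jem, histories, outcomes, model, method, degree, control) {
  ctrl <- fit_control(control)
  yy <- outcomes$case
  warnings <- character()
  if (method != "adjusted") {
    lev <- surrogate_levels(jem, method)
    cummf <- cumulative_exposure(histories, lev)
    df <- outcomes %>% inner_join(cummf, by = "subject_id")
    fam <- if (model == "logistic") binomial() else poisson()
    g <- glm(case ~ cummf, family = fam, data = df)
    est <- coef(g)
    se <- sqrt(diag(vcov(g)))
    return(new_berkson_fit(
      model, method,
      tibble(
        term = c("beta0", "beta1"), estimate = unname(est),
        std.error = unname(se)
      ),
      loglik = as.numeric(stats::logLik(g)),
      converged = g$converged, n = nrow(df), warnings = warnings
    ))
  }
  # adjusted fit: seed from the AM-surrogate fit, box-constrained quasi-Newton
  seed_fit <- fit_unconditional(jem, histories, outcomes, model, "am", degree, control)
  start <- seed_fit$estimates$estimate
  start[1] <- max(start[1], 1e-3) # beta0 >= 0 (series hypothesis)
  start[2] <- max(start[2], 1e-4)
  ord <- outcomes$subject_id
  # finite-difference steps (numerical gradients / hessian) can poke just
  # outside the box; clamp into the series domain before evaluating
  clamp <- function(par, upper) pmin(pmax(par, c(0, 0)), upper)
  st <- spell_table(histories, jem)
  if (model == "logistic") {
    upper <- c(30, if (is.null(ctrl$beta1_upper)) 30 else ctrl$beta1_upper)
    row_of <- match(ord, attr(st, "subjects"))
    nn <- 0:degree
    signs <- rep_len(c(1, -1), degree + 1)
    series_p <- function(beta0, beta1) {
      if (beta1 == 0) {
        return(rep(plogis(beta0), length(attr(st, "subjects"))))
      }
      lf <- rowsum(st$shape * outer(beta1 * st$tc, nn, function(x, n) log1p(n * x)),
        st$idx,
        reorder = TRUE
      )
      clip_prob(drop(exp(-outer(rep(beta0, nrow(lf)), nn, `*`) - lf) %*% signs))
    }
    nll <- function(par) {
      par <- clamp(par, upper)
      p <- series_p(par[1], par[2])[row_of]
      -sum(yy * log(p) + (1 - yy) * log1p(-p))
    }
    gr <- function(par) {
      par <- clamp(par, upper)
      adjusted_logistic_nll_grad(st, par[1], par[2], degree, yy, ord)
    }
  } else {
    vu <- validity_upper(jem, histories, y = setNames(yy, ord)) * (1 - 1e-6)
    # the marginal mean is at least exp(beta0), so the data bound the
    # intercept; without this the optimiser can wander into intercepts where
    # the truncated series has not yet started converging
    b0_up <- log(mean(yy) + 1e-8) + 2
    upper <- c(max(b0_up, 0.1), if (is.null(ctrl$beta1_upper)) vu else min(ctrl$beta1_upper, vu))
    start[1] <- min(start[1], upper[1] * 0.99)
    start[2] <- min(start[2], upper[2] * 0.9)
    nll <- function(par) {
      par <- clamp(par, upper)
      lp <- withCallingHandlers(
        adjusted_poisson_logpmf(yy, histories, jem, par[1], par[2], degree = degree),
        warning = function(w) invokeRestart("muffleWarning")
      )
      -sum(lp$log_pmf[match(ord, lp$subject_id)])
    }
    gr <- NULL
  }
  opt <- optim(start, nll,
    gr = gr, method = "L-BFGS-B",
    lower = c(0, 0), upper = upper,
    control = list(maxit = ctrl$maxit, factr = 1e5),
    hessian = TRUE
  )
  if (opt$convergence != 0) {
    # the Poisson series' integer validity cap makes the objective piecewise
    # in beta1, which can abort the quasi-Newton line search; fall back to a
    # simplex search (the clamped objective enforces the box), trying both
    # the quasi-Newton endpoint and the surrogate-AM seed
    nm <- function(par0) {
      res <- optim(par0, nll,
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-10), hessian = TRUE
      )
      for (restart in 1:3) {
        if (res$convergence == 0) break
        res <- optim(res$par, nll,
          method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10), hessian = TRUE
        )
      }
      res
    }
    candidates <- c(list(opt), lapply(list(opt$par, start), nm))
    vals <- vapply(candidates, function(o) o$value, 0)
    conv <- vapply(candidates, function(o) o$convergence == 0, TRUE)
    tol <- 1e-6 * (1 + abs(min(vals)))
    pick <- if (any(conv & vals <= min(vals) + tol)) {
      which(conv & vals <= min(vals) + tol)[1]
    } else {
      which.min(vals)
    }
    best <- candidates[[pick]]
    best$par <- pmin(pmax(best$par, c(0, 0)), upper)
    opt <- best
  }
  se <- hessian_se(opt$hessian)
  if (opt$convergence != 0) warnings <- c(warnings, paste0("optim: ", opt$message))
  if (!se$ok) warnings <- c(warnings, "Observed information not positive definite.")
  if (opt$par[2] > 0.999 * upper[2]) warnings <- c(warnings, "Estimate at validity boundary.")
  new_berkson_fit(
    model, "adjusted",
    tibble(term = c("beta0", "beta1"), estimate = opt$par, std.error = se$se),
    loglik = -opt$value,
    converged = opt$convergence == 0, n = length(yy), warnings = warnings
  )
}

# analytic gradient of the adjusted-logistic negative log-likelihood
#' @noRd
adjusted_logistic_nll_grad <- function(st, beta0, beta1, degree, yy, ord) {
  subjects <- attr(st, "subjects")
  nn <- 0:degree
  signs <- rep_len(c(1, -1), degree + 1)
  lg <- outer(beta1 * st$tc, nn, function(x, n) log1p(n * x))
  lf <- rowsum(st$shape * lg, st$idx, reorder = TRUE)
  logG <- -outer(rep(beta0, nrow(lf)), nn, `*`) - lf
  terms <- exp(logG)
  p <- clip_prob(drop(terms %*% signs))
  # d log G_{i,n} / d beta1 = -sum_j shape_j * n * tc_j / (1 + n beta1 tc_j)
  dfac <- rowsum(
    st$shape * outer(st$tc, nn, function(tc, n) n * tc / (1 + n * beta1 * tc)),
    st$idx,
    reorder = TRUE
  )
  dp_db0 <- drop((terms * outer(rep(1, nrow(terms)), -nn)) %*% signs)
  dp_db1 <- drop((terms * (-dfac)) %*% signs)
  yo <- yy[match(subjects, ord)]
  w <- yo / p - (1 - yo) / (1 - p)
  -c(sum(w * dp_db0), sum(w * dp_db1))
}

#' @noRd
fit_conditional <- function(jem, histories, outcomes, method, control) {
  ctrl <- fit_control(control)
  if (!("stratum" %in% names(outcomes))) {
    bjem_abort("Conditional-logistic fits need a `stratum` column in outcomes.", "design")
  }
  outcomes <- validate_strata(outcomes)
  warnings <- character()
  # precompute per-subject structures once; the objective is then evaluated
  # hundreds of times inside the line search
  strat <- as.integer(factor(outcomes$stratum))
  is_case <- outcomes$case == 1
  softmax_nll <- function(score) {
    m <- tapply(score, strat, max)[strat]
    e <- exp(score - m)
    denom <- tapply(e, strat, sum)
    -sum(score[is_case] - (m[is_case] + log(denom[strat[is_case]])))
  }
  if (method == "adjusted") {
    st <- spell_table(histories, jem)
    row_of <- match(outcomes$subject_id, attr(st, "subjects"))
    vu <- min(1 / st$tc) * (1 - 1e-6)
    upper <- if (is.null(ctrl$beta1_upper)) vu else min(ctrl$beta1_upper, vu)
    lower <- 0
    nll <- function(b1) {
      score <- rowsum(-st$shape * log1p(-b1 * st$tc), st$idx, reorder = TRUE)[, 1]
      softmax_nll(score[row_of])
    }
  } else {
    lev <- surrogate_levels(jem, method)
    cummf <- cumulative_exposure(histories, lev)
    cm <- cummf$cummf[match(outcomes$subject_id, cummf$subject_id)]
    upper <- if (is.null(ctrl$beta1_upper)) 30 else ctrl$beta1_upper
    lower <- -upper
    nll <- function(b1) softmax_nll(b1 * cm)
  }
  opt <- optimise(nll, c(lower, upper), tol = 1e-9)
  b1 <- opt$minimum
  h <- numeric_second_deriv(nll, b1, lower, upper)
  se <- if (is.finite(h) && h > 0) 1 / sqrt(h) else NA_real_
  if (!is.finite(h) || h <= 0) warnings <- c(warnings, "Observed information not positive.")
  if (b1 > 0.999 * upper) warnings <- c(warnings, "Estimate at validity boundary.")
  new_berkson_fit(
    "conditional-logistic", method,
    tibble(term = "beta1", estimate = b1, std.error = se),
    loglik = -opt$objective,
    converged = TRUE, n = nrow(outcomes), warnings = warnings
  )
}

#' @noRd
numeric_second_deriv <- function(f, x, lower, upper) {
  h <- max(1e-5, abs(x) * 1e-4)
  h <- min(h, (upper - x) / 2, (x - lower) / 2)
  if (h <= 0) return(NA_real_)
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

#' @noRd
hessian_se <- function(H) {
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values, error = function(e) NA)
  ok <- all(is.finite(ev)) && all(ev > 0)
  se <- rep(NA_real_, nrow(H))
  if (ok) {
    se <- sqrt(diag(solve(H)))
  }
  list(ok = ok, se = se)
}

#' @noRd
new_berkson_fit <- function(model, method, estimates, loglik, converged, n, warnings) {
  structure(
    list(
      model = model, method = method, estimates = estimates,
      loglik = loglik, converged = converged, n = n, warnings = warnings
    ),
    class = "berkson_fit"
  )
}

#' Tidy a fitted exposure-response model
#'
#' @param x a `berkson_fit`.
#' @param ... unused.
#' @return tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.berkson_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a fitted exposure-response model
#'
#' @param x a `berkson_fit`.
#' @param ... unused.
#' @return one-row tibble: `model`, `method`, `logLik`, `converged`,
#'   `nobs`, `n_warnings`.
#' @export
glance.berkson_fit <- function(x, ...) {
  tibble(
    model = x$model, method = x$method, logLik = x$loglik,
    converged = x$converged, nobs = x$n, n_warnings = length(x$warnings)
  )
}

#' @export
print.berkson_fit <- function(x, ...) {
  cat("Berkson exposure-response fit\n")
  cat("  model:  ", x$model, "\n  method: ", x$method, "\n", sep = "")
  print(x$estimates)
  cat(
    "  logLik ", format(x$loglik, digits = 6),
    if (!x$converged) "  [NOT CONVERGED]" else "", "\n",
    sep = ""
  )
  if (length(x$warnings)) cat("  warnings: ", paste(x$warnings, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Profile log-likelihood over a slope grid
#'
#' For each fixed `beta1` on `beta1_grid`, the log-likelihood maximised over
#' the intercept (ordinary logistic / Poisson models) or evaluated directly
#' (conditional-logistic, which has no intercept). The grid must stay inside
#' the validity region for adjusted Poisson / conditional methods.
#'
#' @inheritParams fit_exposure_response
#' @param beta1_grid numeric vector of slope values.
#' @return tibble `beta1`, `loglik`.
#' @export
profile_loglik <- function(jem, histories, outcomes, model = BJEM_MODELS,
                           method = BJEM_METHODS, beta1_grid,
                           degree = 10, control = list()) {
  model <- arg_match(model, BJEM_MODELS)
  method <- arg_match(method, BJEM_METHODS)
  jem <- validate_jem(jem)
  outcomes <- as_tibble(outcomes)
  outcomes$subject_id <- as.character(outcomes$subject_id)
  yy <- outcomes$case
  ord <- outcomes$subject_id
  loglik_at <- function(b1) {
    if (model == "conditional-logistic") {
      if (method == "adjusted") {
        return(adjusted_conditional_loglik(outcomes, histories, jem, b1))
      }
      cummf <- cumulative_exposure(histories, surrogate_levels(jem, method))
      return(conditional_logistic_loglik(
        outcomes %>% inner_join(cummf, by = "subject_id"), b1
      ))
    }
    ll_b0 <- function(b0) {
      if (method == "adjusted") {
        if (model == "logistic") {
          p <- adjusted_logistic_prob(histories, jem, b0, b1, degree = degree)
          p <- p$prob[match(ord, p$subject_id)]
          sum(yy * log(p) + (1 - yy) * log1p(-p))
        } else {
          lp <- withCallingHandlers(
            adjusted_poisson_logpmf(yy, histories, jem, b0, b1, degree = degree),
            warning = function(w) invokeRestart("muffleWarning")
          )
          sum(lp$log_pmf[match(ord, lp$subject_id)])
        }
      } else {
        cummf <- cumulative_exposure(histories, surrogate_levels(jem, method))
        eta <- b0 + b1 * cummf$cummf[match(ord, cummf$subject_id)]
        if (model == "logistic") {
          sum(yy * eta - log1p(exp(eta)))
        } else {
          sum(yy * eta - exp(eta) - lfactorial(yy))
        }
      }
    }
    lower_b0 <- if (method == "adjusted") 0 else -30
    optimise(function(b0) -ll_b0(b0), c(lower_b0, 30), tol = 1e-8)$objective * -1
  }
  tibble(beta1 = beta1_grid, loglik = vapply(beta1_grid, loglik_at, 0))
}
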