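# Adaptive-quadrature evaluation of the defining marginal-likelihood
# integrals, independent of the series expansions. Valid for all real beta0,
# beta1 (the series kernels are restricted to beta0 >= 0, beta1 >= 0), and
# used throughout the test suite as the reference the series are checked
# against. Nested one-dimensional adaptive quadrature over each spell's gamma
# density; histories are limited to three spells to keep the nesting exact
# and affordable.

#' Quadrature oracle for the Berkson-adjusted kernels
#'
#' Evaluates, by nested adaptive quadrature over each spell's gamma density,
#' one of the defining integrals of the marginal likelihood for a single
#' subject:
#' * `"logistic-prob"`: `E[plogis(beta0 + beta1 * sum_j t_j X_j)]`,
#' * `"poisson-pmf"`: `E[dpois(y, exp(beta0 + beta1 * sum_j t_j X_j))]`,
#' * `"mean-response"`: `E[exp(beta1 * sum_j t_j X_j)]` (requires the
#'   validity constraint `beta1 * t_j < AM_j/SD_j^2`).
#'
#' @param kind which integral to evaluate.
#' @param history job-history tibble for a single subject (at most 3 spells).
#' @param jem JEM tibble.
#' @param beta0 intercept (any real; ignored for `"mean-response"`).
#' @param beta1 slope (any real).
#' @param y non-negative integer response for `"poisson-pmf"`.
#' @param tol absolute tolerance requested from each quadrature level.
#' @return a single numeric value.
#' @export
quadrature_oracle <- function(kind = c("logistic-prob", "poisson-pmf", "mean-response"),
                              history, jem, beta0 = 0, beta1 = 0, y = 0,
                              tol = 1e-10) {
  kind <- arg_match(kind)
  st <- spell_table(history, jem)
  if (length(attr(st, "subjects")) != 1) {
    bjem_abort("quadrature_oracle() evaluates a single subject's history.", "invalid_input")
  }
  if (nrow(st) > 3) {
    bjem_abort("quadrature_oracle() supports at most 3 spells (nested quadrature).", "invalid_input")
  }
  t_j <- st$duration_years
  shape <- st$shape
  rate <- st$rate
  if (kind == "mean-response" && any(beta1 * t_j >= rate)) {
    bjem_abort(
      "Mean-response integral diverges: beta1 * t >= AM/SD^2 for some spell.",
      "adjustment_undefined"
    )
  }
  if (kind == "mean-response") {
    # E[exp(b1 sum t_j X_j)] factorises over independent spells; each factor
    # is integrated on the log scale so the exponentially growing integrand
    # never overflows against the vanishing gamma density.
    vals <- vapply(seq_along(t_j), function(j) {
      res <- tryCatch(
        integrate(
          function(x) {
            exp(beta1 * t_j[j] * x + dgamma(x, shape = shape[j], rate = rate[j], log = TRUE))
          },
          0, Inf,
          abs.tol = tol, rel.tol = tol * 100, subdivisions = 400L
        ),
        error = function(e) NULL
      )
      if (is.null(res) || !is.finite(res$value)) NA_real_ else res$value
    }, 0)
    if (any(is.na(vals))) {
      bjem_abort("Quadrature failed to converge.", "oracle_failure")
    }
    return(prod(vals))
  }
  integrand <- switch(kind,
    "logistic-prob" = function(s) plogis(beta0 + beta1 * s),
    "poisson-pmf" = function(s) {
      eta <- beta0 + beta1 * s
      # dpois(y, exp(eta)) written to stay finite for extreme eta
      exp(y * eta - exp(eta) - lfactorial(y))
    }
  )
  val <- nested_gamma_integral(integrand, t_j, shape, rate, tol)
  if (is.null(val)) {
    bjem_abort("Quadrature failed to converge.", "oracle_failure")
  }
  val
}

# Integrate fn(sum_j t_j x_j) over independent gamma(x_j; shape_j, rate_j),
# innermost spell first. Each level uses stats::integrate on (0, Inf);
# non-convergence propagates as NULL so the caller can raise a classed error
# instead of silently returning garbage.
#' @noRd
nested_gamma_integral <- function(fn, t_j, shape, rate, tol) {
  level <- function(j, acc) {
    f <- function(x) {
      vapply(x, function(xx) {
        s <- acc + t_j[j] * xx
        if (j == length(t_j)) {
          fn(s)
        } else {
          v <- level(j + 1, s)
          if (is.null(v)) return(NA_real_)
          v
        }
      }, 0) * dgamma(x, shape = shape[j], rate = rate[j])
    }
    res <- tryCatch(
      integrate(f, 0, Inf,
        abs.tol = tol, rel.tol = tol * 100,
        subdivisions = 400L, stop.on.error = TRUE
      ),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) return(NULL)
    res$value
  }
  level(1, 0)
}
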