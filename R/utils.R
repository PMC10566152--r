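# Internal helpers shared across modules.

#' Stop with a classed package error
#'
#' @param message error message
#' @param class error subclass (prefixed with "bjem_error_")
#' @param ... data fields attached to the condition
#' @noRd
bjem_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("bjem_error_", class), "bjem_error"), ...)
}

#' Numerically stable log(sum(exp(x)))
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Signed log-space sum: sum(sign * exp(logabs))
#'
#' Returns the plain-scale value; accurate when positive and negative groups
#' are each accumulated with log-sum-exp before differencing.
#' @noRd
signed_exp_sum <- function(logabs, sign) {
  pos <- sign > 0
  a <- if (any(pos)) exp(log_sum_exp(logabs[pos])) else 0
  b <- if (any(!pos)) exp(log_sum_exp(logabs[!pos])) else 0
  a - b
}

#' Clip probabilities away from 0/1 so log-likelihoods stay finite
#' @noRd
clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Draw n independent substream seeds from a master seed
#'
#' Uses a locally seeded RNG and restores the caller's RNG state, so seed
#' derivation never perturbs other randomness. Seeds stay below 2^31.
#' @noRd
substream_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate a function under a temporary seed, restoring RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
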