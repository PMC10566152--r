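# Synthetic occupational cohort: JEM, job histories, strata, per-spell
# exposure draws, and case/control outcome simulators. The generator stands
# in for a confidential case-control dataset; it emulates the scale and
# covariate structure of a ~800-subject occupational study (gender, age
# group, urban centre) without attempting to reproduce any real job-history
# distribution.
#
# Default value ranges are fixed by two considerations, documented in the
# methods vignette: (i) full-shift ELF magnetic-field levels of a few tenths
# of a microtesla with coefficients of variation below one, and (ii) the
# validity constraint beta1 * t_ij < AM_j/SD_j^2 of the adjusted Poisson /
# conditional likelihoods, which must hold across the whole study slope grid
# (0 to 0.4 per microtesla-year) with margin: the defaults give a worst-case
# bound of 1/(0.8^2 * 0.4 * 6) ~ 0.65.

#' Configuration of the synthetic cohort generator
#'
#' @param n_subjects number of subjects (default 813, the scale of the
#'   Canadian arm of the motivating study).
#' @param n_jobs number of occupation codes in the JEM.
#' @param spells_range integer range of job spells per subject (inclusive).
#' @param duration_range spell duration range in years (uniform).
#' @param am_range range of JEM arithmetic means (microtesla, uniform).
#' @param cv_range range of coefficients of variation `SD/AM` (uniform).
#' @param stratified logical; if `TRUE`, subjects get covariates gender (2
#'   levels) x age group (4) x centre (3) and a `stratum` label from their
#'   interaction (up to 24 strata).
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 813,
                          n_jobs = 50,
                          spells_range = c(1L, 5L),
                          duration_range = c(1, 6),
                          am_range = c(0.1, 0.4),
                          cv_range = c(0.4, 0.8),
                          stratified = FALSE) {
  if (n_subjects < 2) bjem_abort("n_subjects must be at least 2.", "invalid_input")
  if (any(am_range <= 0) || any(cv_range <= 0) || any(duration_range <= 0)) {
    bjem_abort("Ranges must be positive.", "invalid_input")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_jobs = as.integer(n_jobs),
      spells_range = as.integer(spells_range), duration_range = duration_range,
      am_range = am_range, cv_range = cv_range, stratified = isTRUE(stratified)
    ),
    class = "cohort_config"
  )
}

#' Generate a synthetic JEM
#'
#' Draws `AM ~ U(am_range)` and `CV ~ U(cv_range)` (so `SD = CV * AM`) per
#' occupation, then derives `GM` and `GSD` from the gamma law the package
#' assumes for within-occupation exposure: for `X ~ Gamma(r, lambda)`,
#' `E[log X] = digamma(r) - log(lambda)` and `Var[log X] = trigamma(r)`, so
#' `GM = exp(digamma(r)) / lambda` and `GSD = exp(sqrt(trigamma(r)))`. This
#' keeps the JEM internally consistent (`GM < AM`, `GSD > 1`) with the
#' exposure world the simulators draw from.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; same seed gives an identical table.
#' @return a validated JEM tibble.
#' @export
generate_jem <- function(config = cohort_config(), seed = 1) {
  with_seed(seed, {
    am <- runif(config$n_jobs, config$am_range[1], config$am_range[2])
    cv <- runif(config$n_jobs, config$cv_range[1], config$cv_range[2])
    sd <- cv * am
    r <- am^2 / sd^2
    lam <- am / sd^2
    tibble(
      job_code = sprintf("JOB-%03d", seq_len(config$n_jobs)),
      am = am, sd = sd,
      gm = exp(digamma(r)) / lam,
      gsd = exp(sqrt(trigamma(r)))
    ) %>% validate_jem()
  })
}

#' Generate synthetic job histories and subject covariates
#'
#' Each subject holds between `spells_range[1]` and `spells_range[2]` job
#' spells in distinct occupations drawn uniformly from the JEM, with uniform
#' durations. Under a stratified design, subjects additionally receive
#' gender / age-group / centre covariates and the interaction stratum label.
#'
#' @inheritParams generate_jem
#' @param jem a JEM tibble whose job codes the histories reference.
#' @return list with tibbles `histories` (`subject_id`, `job_code`,
#'   `duration_years`) and `subjects` (`subject_id`, plus covariates and
#'   `stratum` when stratified).
#' @export
generate_job_histories <- function(config = cohort_config(), jem, seed = 1) {
  with_seed(seed, {
    ids <- sprintf("S%04d", seq_len(config$n_subjects))
    n_spells <- sample(
      seq(config$spells_range[1], config$spells_range[2]),
      config$n_subjects,
      replace = TRUE
    )
    histories <- tibble(
      subject_id = rep(ids, n_spells),
      job_code = unlist(lapply(n_spells, function(k) sample(jem$job_code, k))),
      duration_years = round(
        runif(sum(n_spells), config$duration_range[1], config$duration_range[2]),
        3
      )
    )
    subjects <- tibble(subject_id = ids)
    if (config$stratified) {
      subjects$gender <- sample(c("F", "M"), config$n_subjects, replace = TRUE)
      subjects$age_group <- sample(c("<40", "40-49", "50-59", "60+"),
        config$n_subjects,
        replace = TRUE
      )
      subjects$centre <- sample(c("C1", "C2", "C3"), config$n_subjects, replace = TRUE)
      subjects$stratum <- paste(subjects$gender, subjects$age_group, subjects$centre,
        sep = "/"
      )
      # strata need one case and at least one control
      sizes <- table(subjects$stratum)
      singletons <- names(sizes)[sizes < 2]
      if (length(singletons) > 0) {
        big <- names(sizes)[which.max(sizes)]
        subjects$stratum[subjects$stratum %in% singletons] <- big
      }
    }
    list(histories = histories, subjects = subjects)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper drawing a JEM and job histories from independent
#' substreams of a single master seed.
#'
#' @inheritParams generate_jem
#' @return list `jem`, `histories`, `subjects`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  seeds <- substream_seeds(seed, 2)
  jem <- generate_jem(config, seeds[1])
  hs <- generate_job_histories(config, jem, seeds[2])
  list(
    jem = jem, histories = hs$histories, subjects = hs$subjects,
    config = config, seed = seed
  )
}

#' Draw per-spell exposures from the gamma model
#'
#' Each spell's exposure is drawn independently from
#' `Gamma(shape = (AM_j/SD_j)^2, scale = SD_j^2/AM_j)` for its occupation, so
#' the draw has mean `AM_j` and standard deviation `SD_j`.
#'
#' @param histories job-history tibble.
#' @param jem JEM tibble.
#' @param seed integer seed.
#' @return `histories` with a per-spell exposure column `x` (microtesla)
#'   appended.
#' @export
sample_exposures <- function(histories, jem, seed = 1) {
  st <- spell_table(histories, jem)
  with_seed(seed, {
    x <- rgamma(nrow(st), shape = st$shape, rate = st$rate)
    tibble(
      subject_id = st$subject_id, job_code = st$job_code,
      duration_years = st$duration_years, x = x
    )
  })
}

#' Simulate case status, non-stratified design
#'
#' Each subject's case probability is the standard logistic
#' `plogis(beta0 + beta1 * cummf)`, and case statuses are independent
#' Bernoulli draws.
#'
#' @param cummf tibble `subject_id`, `cummf` (e.g. from
#'   [cumulative_exposure()] on sampled exposures).
#' @param beta0,beta1 true intercept and slope.
#' @param seed integer seed.
#' @return tibble `subject_id`, `case`.
#' @export
simulate_outcomes_nonstratified <- function(cummf, beta0, beta1, seed = 1) {
  cummf <- as_tibble(cummf)
  if (any(cummf$cummf < 0)) bjem_abort("cummf must be non-negative.", "invalid_input")
  p <- plogis(beta0 + beta1 * cummf$cummf)
  with_seed(seed, {
    tibble(subject_id = cummf$subject_id, case = rbinom(nrow(cummf), 1L, p))
  })
}

#' Simulate case status, stratified design
#'
#' Within each stratum exactly one subject becomes the case, drawn from a
#' single-trial multinomial whose probabilities are the SoftMax of
#' `beta1 * cummf` over the stratum's subjects (each subject's own cumulative
#' exposure).
#'
#' @param data tibble `subject_id`, `stratum`, `cummf`.
#' @param beta1 true slope.
#' @param seed integer seed.
#' @return tibble `subject_id`, `stratum`, `case` with one case per stratum.
#' @export
simulate_outcomes_stratified <- function(data, beta1, seed = 1) {
  data <- as_tibble(data)
  if (!all(c("subject_id", "stratum", "cummf") %in% names(data))) {
    bjem_abort("`data` must have columns subject_id, stratum, cummf.", "invalid_input")
  }
  scored <- stratum_case_probs(data %>% mutate(score = beta1 * .data$cummf))
  with_seed(seed, {
    out <- scored %>%
      group_by(.data$stratum) %>%
      mutate(case = {
        idx <- sample.int(dplyr::n(), 1L, prob = .data$prob)
        as.integer(seq_len(dplyr::n()) == idx)
      }) %>%
      ungroup()
    out %>% select("subject_id", "stratum", "case")
  })
}
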