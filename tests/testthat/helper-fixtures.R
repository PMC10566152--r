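# Shared fixtures, built in code. toy_jem() rows are chosen so closed forms
# are easy to verify by hand: J1 has shape 1 (exponential), J2 shape 4.

toy_jem <- function() {
  tibble::tibble(
    job_code = c("J1", "J2", "J3"),
    am = c(0.15, 0.4, 0.25),
    sd = c(0.15, 0.2, 0.2),
    gm = c(0.10, 0.35, 0.18),
    gsd = c(2.0, 1.5, 1.8)
  )
}

one_spell <- function(t = 10, job = "J1", id = "S1") {
  tibble::tibble(subject_id = id, job_code = job, duration_years = t)
}

two_spells <- function(id = "S1") {
  tibble::tibble(
    subject_id = id,
    job_code = c("J1", "J2"),
    duration_years = c(10, 5)
  )
}

# small matched design: two strata, one case each
toy_strata <- function() {
  tibble::tibble(
    subject_id = sprintf("S%d", 1:6),
    stratum = c("a", "a", "a", "b", "b", "b"),
    case = c(1L, 0L, 0L, 0L, 1L, 0L),
    cummf = c(2, 1, 3, 0.5, 2.5, 1)
  )
}

# cohort with exposures and non-stratified outcomes, for fit tests
sim_cohort_outcomes <- function(n = 200, beta0 = 1, beta1 = 0.2, seed = 42,
                                stratified = FALSE) {
  co <- generate_cohort(cohort_config(n_subjects = n, stratified = stratified), seed)
  ex <- sample_exposures(co$histories, co$jem, seed + 1)
  cm <- cumulative_exposure(ex)
  if (stratified) {
    cm2 <- dplyr::inner_join(
      cm, dplyr::select(co$subjects, subject_id, stratum),
      by = "subject_id"
    )
    outcomes <- simulate_outcomes_stratified(cm2, beta1, seed + 2)
  } else {
    outcomes <- simulate_outcomes_nonstratified(cm, beta0, beta1, seed + 2)
  }
  list(cohort = co, exposures = ex, cummf = cm, outcomes = outcomes)
}
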