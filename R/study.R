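# Two-level Monte Carlo study comparing slope estimators.
#
# For each true slope on the grid, the outer loop re-draws per-spell
# exposures (and hence true cumulative exposures) with the JEM and job
# histories held fixed; the inner loop re-draws case/control outcomes from
# those exposures and re-estimates the slope by each method. Per outer
# replicate the MEDIAN of the inner estimates is recorded (the estimate
# distribution is right-skewed); across outer replicates the mean and the
# 2.5% / 97.5% percentiles of those medians are reported. The variance
# entering SE and RMSE is the total variance: the mean of the
# within-outer-replicate (conditional) variances of the raw inner estimates
# plus the variance of the conditional means, both in population form so the
# decomposition is exact.

#' Configuration of the simulation study
#'
#' Defaults match the full study design (813 subjects, slope grid 0 to 0.4 in
#' steps of 0.01, 100 outer x 100 inner replicates, intercept 1); that preset
#' takes hours. [study_config_reduced()] is the desk-scale preset used by the
#' test suite (200 subjects, grid {0.1, 0.2, 0.3}, 20 x 20 replicates).
#'
#' @param beta0 true intercept (non-stratified design only).
#' @param beta1_grid vector of true slopes; must stay inside the adjusted
#'   methods' validity region for the generated JEM.
#' @param n_outer outer replicates (exposure re-draws).
#' @param n_inner inner replicates (outcome re-draws).
#' @param methods estimators to compare (subset of
#'   `c("adjusted","am","gm","mgm")`).
#' @param degree series truncation degree for adjusted fits.
#' @param design `"non-stratified"` (ordinary logistic) or `"stratified"`
#'   (conditional logistic; `beta0` unused).
#' @param cohort a [cohort_config()]; its `stratified` flag is forced to
#'   match `design`.
#' @param n_cores worker processes (forked); results are identical for any
#'   value because every (slope, outer) cell seeds its own substream.
#' @param seed master seed.
#' @return a `study_config` list.
#' @export
study_config <- function(beta0 = 1,
                         beta1_grid = seq(0, 0.4, by = 0.01),
                         n_outer = 100,
                         n_inner = 100,
                         methods = c("adjusted", "am", "gm", "mgm"),
                         degree = 10,
                         design = c("non-stratified", "stratified"),
                         cohort = cohort_config(),
                         n_cores = 1,
                         seed = 1) {
  design <- arg_match(design)
  methods <- match.arg(methods, BJEM_METHODS, several.ok = TRUE)
  if (n_outer < 1 || n_inner < 1) bjem_abort("Replicate counts must be >= 1.", "invalid_input")
  cohort$stratified <- design == "stratified"
  structure(
    list(
      beta0 = beta0, beta1_grid = beta1_grid, n_outer = as.integer(n_outer),
      n_inner = as.integer(n_inner), methods = methods, degree = degree,
      design = design, cohort = cohort, n_cores = as.integer(n_cores),
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @rdname study_config
#' @param ... overrides passed to [study_config()].
#' @export
study_config_reduced <- function(...) {
  defaults <- list(
    beta1_grid = c(0.1, 0.2, 0.3), n_outer = 20, n_inner = 20,
    cohort = cohort_config(n_subjects = 200)
  )
  do.call(study_config, modifyList(defaults, list(...)))
}

#' Run the two-level simulation study
#'
#' @param config a [study_config()].
#' @return a `berkson_study` object: list with `results` (one row per
#'   (true slope, method): mean of outer medians, percentiles, bias, total
#'   variance, SE, RMSE, replicate and failure counts), `estimates` (every
#'   raw inner estimate), `config`, and the fixed `cohort`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seeds <- substream_seeds(config$seed, 1 + length(config$beta1_grid) * config$n_outer)
  cohort <- generate_cohort(config$cohort, seeds[1])
  cell_seeds <- matrix(seeds[-1], nrow = length(config$beta1_grid)) # grid x outer
  cells <- tidyr::expand_grid(
    g = seq_along(config$beta1_grid),
    outer = seq_len(config$n_outer)
  )
  run_cell <- function(row) {
    g <- cells$g[row]
    outer_rep <- cells$outer[row]
    study_cell(
      config, cohort, config$beta1_grid[g], outer_rep,
      cell_seeds[g, outer_rep]
    )
  }
  res_list <- if (config$n_cores > 1) {
    parallel::mclapply(seq_len(nrow(cells)), run_cell, mc.cores = config$n_cores)
  } else {
    lapply(seq_len(nrow(cells)), run_cell)
  }
  estimates <- bind_rows(res_list)
  results <- estimates %>%
    group_by(.data$beta1_true, .data$method) %>%
    dplyr::group_modify(~ compute_metrics(.x, .y$beta1_true)) %>%
    ungroup()
  structure(
    list(results = results, estimates = estimates, config = config, cohort = cohort),
    class = "berkson_study"
  )
}

# One (true slope, outer replicate) cell: draw exposures once, then re-draw
# outcomes and refit n_inner times for every method.
#' @noRd
study_cell <- function(config, cohort, beta1_true, outer_rep, cell_seed) {
  sub_seeds <- substream_seeds(cell_seed, 1 + config$n_inner)
  exposed <- sample_exposures(cohort$histories, cohort$jem, sub_seeds[1])
  cummf <- cumulative_exposure(exposed)
  out <- vector("list", config$n_inner)
  for (inner in seq_len(config$n_inner)) {
    if (config$design == "non-stratified") {
      outcomes <- simulate_outcomes_nonstratified(
        cummf, config$beta0, beta1_true, sub_seeds[1 + inner]
      )
      model <- "logistic"
    } else {
      strata <- cohort$subjects %>% select("subject_id", "stratum")
      outcomes <- simulate_outcomes_stratified(
        cummf %>% inner_join(strata, by = "subject_id"),
        beta1_true, sub_seeds[1 + inner]
      )
      model <- "conditional-logistic"
    }
    ests <- lapply(config$methods, function(m) {
      fit <- tryCatch(
        withCallingHandlers(
          fit_exposure_response(
            cohort$jem, cohort$histories, outcomes,
            model = model, method = m, degree = config$degree
          ),
          warning = function(w) invokeRestart("muffleWarning")
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble(method = m, estimate = NA_real_, converged = FALSE))
      }
      b1 <- fit$estimates$estimate[fit$estimates$term == "beta1"]
      tibble(method = m, estimate = b1, converged = fit$converged)
    })
    out[[inner]] <- bind_rows(ests) %>%
      mutate(inner = inner)
  }
  bind_rows(out) %>%
    mutate(beta1_true = beta1_true, outer = outer_rep)
}

#' @noRd
study_metrics <- function(df) {
  truth <- df$beta1_true[1]
  compute_metrics(df %>% select("outer", "estimate", "converged"), truth)
}

#' Bias, SE, and RMSE from nested replicate estimates
#'
#' Given raw inner estimates grouped by outer replicate, computes the study's
#' summary metrics: per-outer medians, their mean and 2.5%/97.5% percentiles;
#' `bias = mean(medians) - truth`; `total_variance` = mean of the
#' within-outer (conditional) population variances of the raw estimates plus
#' the population variance of the conditional means (exactly the pooled
#' population variance of all estimates for equal-sized replicates);
#' `se = sqrt(total_variance)`; `rmse = sqrt(total_variance + bias^2)`.
#' Non-converged or failed estimates are excluded and counted in `n_failed`.
#'
#' @param estimates tibble with columns `outer`, `estimate`, and optionally
#'   `converged`.
#' @param truth the true slope.
#' @return one-row tibble of metrics.
#' @export
compute_metrics <- function(estimates, truth) {
  estimates <- as_tibble(estimates)
  if (!all(c("outer", "estimate") %in% names(estimates))) {
    bjem_abort("`estimates` must have columns outer and estimate.", "invalid_input")
  }
  if (!("converged" %in% names(estimates))) estimates$converged <- TRUE
  n_total <- nrow(estimates)
  ok <- estimates %>% filter(.data$converged, is.finite(.data$estimate))
  n_failed <- n_total - nrow(ok)
  if (nrow(ok) == 0) {
    return(tibble(
      mean_estimate = NA_real_, p2.5 = NA_real_, p97.5 = NA_real_,
      bias = NA_real_, total_variance = NA_real_, se = NA_real_,
      rmse = NA_real_, mcse = NA_real_, n_estimates = 0L, n_failed = n_failed
    ))
  }
  pop_var <- function(x) mean((x - mean(x))^2)
  per_outer <- ok %>%
    group_by(.data$outer) %>%
    summarise(
      med = median(.data$estimate),
      cond_mean = mean(.data$estimate),
      cond_var = pop_var(.data$estimate),
      .groups = "drop"
    )
  mean_est <- mean(per_outer$med)
  bias <- mean_est - truth
  total_variance <- mean(per_outer$cond_var) + pop_var(per_outer$cond_mean)
  tibble(
    mean_estimate = mean_est,
    p2.5 = unname(quantile(per_outer$med, 0.025)),
    p97.5 = unname(quantile(per_outer$med, 0.975)),
    bias = bias,
    total_variance = total_variance,
    se = sqrt(total_variance),
    rmse = sqrt(total_variance + bias^2),
    mcse = sd(per_outer$med) / sqrt(nrow(per_outer)),
    n_estimates = nrow(ok),
    n_failed = n_failed
  )
}

#' @export
print.berkson_study <- function(x, ...) {
  cat(
    "Berkson simulation study (", x$config$design, "), ",
    length(x$config$beta1_grid), " slope value(s), ",
    x$config$n_outer, " x ", x$config$n_inner, " replicates\n",
    sep = ""
  )
  print(x$results, n = Inf)
  invisible(x)
}

#' Plot study metrics against the true slope
#'
#' @param object a `berkson_study`.
#' @param metric which metric to draw.
#' @param ... unused.
#' @return a ggplot; one line per method, failed cells left as gaps.
#' @export
autoplot.berkson_study <- function(object, metric = c("bias", "se", "rmse"), ...) {
  metric <- arg_match(metric)
  df <- object$results
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$beta1_true, y = .data[[metric]],
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(beta[1] ~ "(true slope, per " * mu * "T-year)"),
      y = metric,
      colour = "method"
    ) +
    ggplot2::theme_minimal()
}

#' Write study tables, figures, and provenance to a directory
#'
#' Writes `results.csv` (all cells, full double precision so re-reading
#' reproduces the values exactly), `estimates.csv` (raw inner estimates),
#' `bias.png` / `se.png` / `rmse.png`, and `provenance.json` (configuration,
#' master seed, package version).
#'
#' @param study a `berkson_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
report_study <- function(study, dir) {
  stopifnot(inherits(study, "berkson_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$results, file.path(dir, "results.csv"))
  readr::write_csv(study$estimates, file.path(dir, "estimates.csv"))
  for (m in c("bias", "se", "rmse")) {
    ggplot2::ggsave(
      file.path(dir, paste0(m, ".png")),
      autoplot(study, m),
      width = 6, height = 4, dpi = 120
    )
  }
  cfg <- study$config
  cfg$cohort <- unclass(cfg$cohort)
  jsonlite::write_json(
    list(
      config = unclass(cfg),
      package_version = as.character(packageVersion("berksonjem")),
      generated = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    file.path(dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
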