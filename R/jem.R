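# JEM tables, job histories, surrogate levels, and cumulative exposure.
#
# A JEM (job-exposure matrix) is a tibble with one row per occupation code and
# columns `job_code`, `am`, `sd` (arithmetic mean and standard deviation of
# full-shift exposure, in microtesla), and optionally `gm`, `gsd` (geometric
# mean and geometric standard deviation). Job histories are tibbles with one
# row per (subject, job spell): `subject_id`, `job_code`, `duration_years`.
# Outcomes are tibbles `subject_id`, `case` (0/1, or a count for Poisson
# models) and optionally `stratum`.

#' Validate a JEM table
#'
#' Checks column presence and the invariants that make the gamma
#' parameterisation well defined: `am > 0`, `sd > 0`, unique `job_code`, and,
#' where present (non-missing), `gm > 0` and `gsd >= 1`. `gm`/`gsd` may be
#' absent or `NA` when only AM-based methods are used.
#'
#' @param jem data frame with columns `job_code`, `am`, `sd` and optionally
#'   `gm`, `gsd`.
#' @return the validated JEM as a tibble (with `gm`/`gsd` columns added as
#'   `NA` if absent), invisibly usable in pipelines.
#' @export
validate_jem <- function(jem) {
  jem <- as_tibble(jem)
  required <- c("job_code", "am", "sd")
  missing_cols <- setdiff(required, names(jem))
  if (length(missing_cols) > 0) {
    bjem_abort(
      paste0("JEM is missing column(s): ", paste(missing_cols, collapse = ", ")),
      "invalid_jem"
    )
  }
  if (nrow(jem) == 0) {
    bjem_abort("JEM table is empty.", "empty_input")
  }
  if (!("gm" %in% names(jem))) jem$gm <- NA_real_
  if (!("gsd" %in% names(jem))) jem$gsd <- NA_real_
  jem$job_code <- as.character(jem$job_code)
  for (col in c("am", "sd", "gm", "gsd")) {
    if (!is.numeric(jem[[col]])) {
      bjem_abort(paste0("JEM column '", col, "' must be numeric."), "invalid_jem")
    }
  }
  dup <- jem$job_code[duplicated(jem$job_code)]
  if (length(dup) > 0) {
    bjem_abort(
      paste0("Duplicate job_code(s) in JEM: ", paste(unique(dup), collapse = ", ")),
      "duplicate_key"
    )
  }
  bad <- which(!is.finite(jem$am) | !is.finite(jem$sd) | jem$am <= 0 | jem$sd <= 0)
  if (length(bad) > 0) {
    bjem_abort(
      paste0(
        "JEM rows with non-positive or missing am/sd (gamma model undefined): row(s) ",
        paste(bad, collapse = ", "),
        " [job_code ", paste(jem$job_code[bad], collapse = ", "), "]"
      ),
      "invalid_jem",
      rows = bad
    )
  }
  bad_gm <- which(!is.na(jem$gm) & jem$gm <= 0)
  bad_gsd <- which(!is.na(jem$gsd) & jem$gsd < 1)
  if (length(bad_gm) > 0 || length(bad_gsd) > 0) {
    bjem_abort(
      paste0(
        "JEM rows with invalid gm (<= 0) or gsd (< 1): row(s) ",
        paste(sort(unique(c(bad_gm, bad_gsd))), collapse = ", ")
      ),
      "invalid_jem",
      rows = sort(unique(c(bad_gm, bad_gsd)))
    )
  }
  jem[, c("job_code", "am", "sd", "gm", "gsd")]
}

#' Gamma parameterisation of a JEM
#'
#' Adds the per-occupation gamma parameters implied by the JEM summaries:
#' shape `r = am^2 / sd^2` and rate `lambda = am / sd^2` (per microtesla), so
#' that the gamma mean is `am` and its variance `sd^2`.
#'
#' @inheritParams validate_jem
#' @return the JEM tibble with columns `shape` and `rate` appended.
#' @examples
#' jem <- tibble::tibble(job_code = "J1", am = 2, sd = 1)
#' jem_gamma_params(jem) # shape 4, rate 2
#' @export
jem_gamma_params <- function(jem) {
  jem <- validate_jem(jem)
  jem %>% mutate(shape = .data$am^2 / .data$sd^2, rate = .data$am / .data$sd^2)
}

#' Surrogate exposure levels from a JEM
#'
#' Returns the deterministic exposure level each surrogate assigns to every
#' occupation: `"am"` the arithmetic mean; `"gm"` the geometric mean; `"mgm"`
#' the modified geometric mean, taken as the log-normal mean
#' `gm * exp(log(gsd)^2 / 2)` (the mean of the log-normal distribution with
#' median `gm` and geometric standard deviation `gsd`).
#'
#' @inheritParams validate_jem
#' @param kind one of `"am"`, `"gm"`, `"mgm"`.
#' @return tibble with columns `job_code`, `level` (microtesla).
#' @export
surrogate_levels <- function(jem, kind = c("am", "gm", "mgm")) {
  kind <- arg_match(kind)
  jem <- validate_jem(jem)
  level <- switch(kind,
    am = jem$am,
    gm = jem$gm,
    mgm = jem$gm * exp(log(jem$gsd)^2 / 2)
  )
  if (kind != "am") {
    bad <- which(is.na(jem$gm) | is.na(jem$gsd))
    if (kind == "gm") bad <- which(is.na(jem$gm))
    if (length(bad) > 0) {
      bjem_abort(
        paste0(
          "Surrogate '", kind, "' needs gm/gsd but they are missing for job_code(s): ",
          paste(jem$job_code[bad], collapse = ", ")
        ),
        "missing_field"
      )
    }
  }
  tibble(job_code = jem$job_code, level = level)
}

#' Cumulative exposure from job histories
#'
#' Computes each subject's cumulative exposure
#' `CumMF_i = sum_j t_ij * x_ij` (microtesla-years), where `t_ij` are spell
#' durations and `x_ij` per-spell exposure levels. Levels are either a
#' per-occupation table (`job_code`, `level`), e.g. from
#' [surrogate_levels()], or a per-spell column `x` already present in
#' `histories` (as produced by [sample_exposures()]).
#'
#' @param histories job-history tibble (`subject_id`, `job_code`,
#'   `duration_years`, optionally `x`).
#' @param levels optional tibble (`job_code`, `level`); ignored when
#'   `histories` carries a per-spell `x` column and `levels` is `NULL`.
#' @return tibble `subject_id`, `cummf`, one row per subject, in first-seen
#'   subject order.
#' @export
cumulative_exposure <- function(histories, levels = NULL) {
  histories <- validate_histories(histories, require_x = is.null(levels))
  if (!is.null(levels)) {
    levels <- as_tibble(levels)
    if (!all(c("job_code", "level") %in% names(levels))) {
      bjem_abort("`levels` must have columns job_code and level.", "invalid_input")
    }
    unresolved <- setdiff(histories$job_code, as.character(levels$job_code))
    if (length(unresolved) > 0) {
      bjem_abort(
        paste0(
          "Job code(s) in histories without an exposure level: ",
          paste(unresolved, collapse = ", ")
        ),
        "lookup"
      )
    }
    histories <- histories %>%
      left_join(
        levels %>% mutate(job_code = as.character(.data$job_code)),
        by = "job_code"
      ) %>%
      mutate(x = .data$level)
  }
  histories %>%
    mutate(subject_id = factor(.data$subject_id, levels = unique(.data$subject_id))) %>%
    group_by(.data$subject_id) %>%
    summarise(cummf = sum(.data$duration_years * .data$x), .groups = "drop") %>%
    mutate(subject_id = as.character(.data$subject_id))
}

#' @noRd
validate_histories <- function(histories, require_x = FALSE) {
  histories <- as_tibble(histories)
  required <- c("subject_id", "job_code", "duration_years")
  missing_cols <- setdiff(required, names(histories))
  if (length(missing_cols) > 0) {
    bjem_abort(
      paste0("Histories missing column(s): ", paste(missing_cols, collapse = ", ")),
      "invalid_input"
    )
  }
  if (nrow(histories) == 0) {
    bjem_abort("Histories table is empty.", "empty_input")
  }
  if (!is.numeric(histories$duration_years) ||
    any(!is.finite(histories$duration_years) | histories$duration_years <= 0)) {
    bad <- which(!is.finite(histories$duration_years) | histories$duration_years <= 0)
    bjem_abort(
      paste0("Non-positive spell duration(s) at row(s): ", paste(bad, collapse = ", ")),
      "invalid_input",
      rows = bad
    )
  }
  if (require_x && !("x" %in% names(histories))) {
    bjem_abort(
      "Histories carry no per-spell exposure column `x` and no `levels` were given.",
      "invalid_input"
    )
  }
  histories$subject_id <- as.character(histories$subject_id)
  histories$job_code <- as.character(histories$job_code)
  histories
}

#' Join job histories with JEM gamma parameters
#'
#' Internal workhorse: one row per spell with duration, `am`, `shape`, and
#' `cv2t = duration * sd^2 / am` (the factor multiplying the slope inside each
#' gamma MGF evaluation), plus a dense subject index in first-seen order.
#' @noRd
spell_table <- function(histories, jem) {
  histories <- validate_histories(histories)
  jem <- jem_gamma_params(jem)
  unresolved <- setdiff(histories$job_code, jem$job_code)
  if (length(unresolved) > 0) {
    bjem_abort(
      paste0(
        "Job code(s) in histories not present in the JEM: ",
        paste(unresolved, collapse = ", ")
      ),
      "lookup"
    )
  }
  st <- histories %>%
    left_join(jem, by = "job_code") %>%
    mutate(
      inv_rate = .data$sd^2 / .data$am, # 1 / lambda
      tc = .data$duration_years * .data$inv_rate
    )
  subj <- unique(st$subject_id)
  st$idx <- match(st$subject_id, subj)
  attr(st, "subjects") <- subj
  st
}

# ---- CSV I/O ----------------------------------------------------------------

#' Read and write JEM, history, and outcome CSV files
#'
#' File formats (UTF-8, comma-separated, decimal point):
#' * JEM: header `job_code,am,sd,gm,gsd` (`gm`,`gsd` may be empty).
#' * Histories: header `subject_id,job_code,duration_years`, one row per spell.
#' * Outcomes: header `subject_id,case` and optionally `stratum`.
#'
#' Reading validates records (duplicate `job_code`, non-positive `am`/`sd`,
#' non-positive durations, malformed numeric fields all raise classed errors
#' naming the offending rows); writing preserves full double precision so a
#' write/read round trip reproduces values exactly.
#'
#' @param path file path.
#' @return a validated tibble.
#' @export
read_jem <- function(path) {
  df <- read_strict_csv(path, c("job_code", "am", "sd"))
  validate_jem(df)
}

#' @rdname read_jem
#' @export
read_job_histories <- function(path) {
  df <- read_strict_csv(path, c("subject_id", "job_code", "duration_years"))
  validate_histories(df)
}

#' @rdname read_jem
#' @export
read_outcomes <- function(path) {
  df <- read_strict_csv(path, c("subject_id", "case"))
  df$subject_id <- as.character(df$subject_id)
  if (!is.numeric(df$case) || any(!is.finite(df$case) | df$case < 0 | df$case != round(df$case))) {
    bjem_abort("Outcome column `case` must hold non-negative integers.", "invalid_input")
  }
  if ("stratum" %in% names(df)) df$stratum <- as.character(df$stratum)
  df
}

#' @noRd
read_strict_csv <- function(path, required) {
  if (!file.exists(path)) {
    bjem_abort(paste0("File not found: ", path), "io")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) bjem_abort(paste0("Failed to parse ", path, ": ", conditionMessage(e)), "io")
  )
  if (nrow(df) == 0) {
    bjem_abort(paste0("Empty input file: ", path), "empty_input")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    bjem_abort(
      paste0(
        "Malformed field(s) in ", path, " at row(s): ",
        paste(unique(probs$row), collapse = ", ")
      ),
      "io"
    )
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    bjem_abort(
      paste0(path, " is missing column(s): ", paste(missing_cols, collapse = ", ")),
      "io"
    )
  }
  df
}

#' @rdname read_jem
#' @param x tibble to write.
#' @export
write_jem <- function(x, path) {
  readr::write_csv(validate_jem(x), path)
  invisible(path)
}

#' @rdname read_jem
#' @export
write_job_histories <- function(x, path) {
  readr::write_csv(validate_histories(x), path)
  invisible(path)
}

#' @rdname read_jem
#' @export
write_outcomes <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}
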