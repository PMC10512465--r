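#' Session configuration for an alternating form/motion session
#'
#' A session interleaves form (Glass-pattern) and motion (optic-flow) trials,
#' one judged feature per trial: the horizontal angle of the form or motion
#' focus of expansion (FoE). Defaults describe a 1,320-trial session (660
#' trials per modality) starting with a form trial, with FoE angles drawn
#' uniformly from a 1-degree grid on \[-45, 45\] degrees.
#'
#' @param n_trials_per_modality Trials per modality (session length is twice
#'   this). Must be at least 2.
#' @param foe_min_deg,foe_max_deg,foe_step_deg FoE angle grid, in degrees.
#' @param start_modality `"form"` or `"motion"`; the modality of trial 1.
#' @param form_density,motion_density Dot-density level (`"low"` or `"high"`)
#'   of each display type, carried as a per-trial label.
#'
#' @return An object of class `session_config` (a named list).
#' @seealso [simulate_session()], [observer_params()]
#' @export
#' @examples
#' session_config()
#' session_config(n_trials_per_modality = 100, motion_density = "low")
session_config <- function(n_trials_per_modality = 660,
                           foe_min_deg = -45, foe_max_deg = 45,
                           foe_step_deg = 1,
                           start_modality = c("form", "motion"),
                           form_density = c("high", "low"),
                           motion_density = c("high", "low")) {
  start_modality <- match.arg(start_modality)
  form_density <- match.arg(form_density)
  motion_density <- match.arg(motion_density)
  if (!is.numeric(n_trials_per_modality) || n_trials_per_modality < 2 ||
      n_trials_per_modality != round(n_trials_per_modality)) {
    abort("`n_trials_per_modality` must be an integer >= 2.")
  }
  if (foe_min_deg >= foe_max_deg) abort("`foe_min_deg` must be < `foe_max_deg`.")
  if (foe_step_deg <= 0) abort("`foe_step_deg` must be positive.")
  structure(
    list(
      n_trials_per_modality = as.integer(n_trials_per_modality),
      foe_min_deg = foe_min_deg, foe_max_deg = foe_max_deg,
      foe_step_deg = foe_step_deg,
      start_modality = start_modality,
      form_density = form_density, motion_density = motion_density
    ),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  trials: %d (%d per modality), starting with a %s trial\n",
              2L * x$n_trials_per_modality, x$n_trials_per_modality,
              x$start_modality))
  cat(sprintf("  FoE grid: [%g, %g] deg, step %g deg\n",
              x$foe_min_deg, x$foe_max_deg, x$foe_step_deg))
  cat(sprintf("  density: form %s, motion %s\n",
              x$form_density, x$motion_density))
  invisible(x)
}

foe_grid <- function(config) {
  seq(config$foe_min_deg, config$foe_max_deg, by = config$foe_step_deg)
}

trial_log_columns <- c("participant_id", "trial_index", "modality", "density",
                       "true_foe_deg", "perceived_foe_deg")

#' Validate a trial log
#'
#' Checks that a data frame of trials has the expected columns and types,
#' legal modality/density tokens, and optionally that each participant's
#' trials form a valid session: contiguous 1-based trial indices and strict
#' form/motion alternation. Perceived angles are deliberately not range
#' checked: the response probe may report values outside the stimulus grid
#' and the regression must see them unmodified.
#'
#' @param trials A data frame with columns `participant_id`, `trial_index`,
#'   `modality`, `density`, `true_foe_deg`, `perceived_foe_deg`.
#' @param session If `TRUE`, additionally require per-participant contiguity
#'   and modality alternation.
#' @param line_offset Added to row indices in error messages (used by
#'   [read_trial_log()] to account for the header line).
#' @return `trials` as a tibble, invisibly usable in a pipe; errors describe
#'   the offending line and column.
#' @export
validate_trial_log <- function(trials, session = FALSE, line_offset = 0) {
  trials <- tibble::as_tibble(trials)
  missing <- setdiff(trial_log_columns, names(trials))
  if (length(missing) > 0) {
    abort(paste0("trial log is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_mod <- which(!trials$modality %in% MODALITIES)
  if (length(bad_mod) > 0) {
    abort(sprintf("line %d, column modality: unknown token \"%s\"",
                  bad_mod[1] + line_offset, trials$modality[bad_mod[1]]))
  }
  bad_den <- which(!trials$density %in% DENSITIES)
  if (length(bad_den) > 0) {
    abort(sprintf("line %d, column density: unknown token \"%s\"",
                  bad_den[1] + line_offset, trials$density[bad_den[1]]))
  }
  for (col in c("true_foe_deg", "perceived_foe_deg")) {
    bad <- which(!is.finite(trials[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("line %d, column %s: non-numeric or missing angle",
                    bad[1] + line_offset, col))
    }
  }
  dup <- duplicated(trials[, c("participant_id", "trial_index")])
  if (any(dup)) {
    key <- trials[which(dup)[1], ]
    abort(sprintf("duplicate (participant_id, trial_index) pair: (%s, %d)",
                  key$participant_id, key$trial_index))
  }
  if (session) {
    split_idx <- split(seq_len(nrow(trials)), trials$participant_id)
    for (pid in names(split_idx)) {
      rows <- trials[split_idx[[pid]], ]
      rows <- rows[order(rows$trial_index), ]
      if (!identical(as.integer(rows$trial_index), seq_len(nrow(rows)))) {
        abort(sprintf("participant %s: trial_index not contiguous from 1", pid))
      }
      start <- rows$modality[1]
      expected <- rep_len(c(start, other_modality(start)), nrow(rows))
      off <- which(rows$modality != expected)
      if (length(off) > 0) {
        abort(sprintf(
          "participant %s: modality does not alternate at trial_index %d",
          pid, rows$trial_index[off[1]]))
      }
    }
  }
  invisible(trials)
}

#' Write a trial log to CSV
#'
#' The package's single interchange format: comma-separated, UTF-8, header
#' `participant_id,trial_index,modality,density,true_foe_deg,perceived_foe_deg`,
#' '.' decimal separator, angles at full double precision so that
#' [read_trial_log()] restores the records exactly.
#'
#' @param trials Trial-log data frame, sorted by (participant_id, trial_index).
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  trials <- validate_trial_log(trials)
  if (nrow(trials) > 0) {
    ord <- order(trials$participant_id, trials$trial_index)
    if (!identical(ord, seq_len(nrow(trials)))) {
      abort("records must be sorted by (participant_id, trial_index)")
    }
  }
  readr::write_csv(trials[, trial_log_columns], path)
  invisible(path)
}

#' Read a trial log from CSV
#'
#' @param path Source file in the dialect written by [write_trial_log()].
#' @param session Passed to [validate_trial_log()]: also check per-participant
#'   contiguity and modality alternation.
#' @return A tibble of trials, validated; parse or validation failures error
#'   with the offending line and column.
#' @export
read_trial_log <- function(path, session = FALSE) {
  trials <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      trial_index = readr::col_integer(),
      modality = readr::col_character(),
      density = readr::col_character(),
      true_foe_deg = readr::col_double(),
      perceived_foe_deg = readr::col_double()
    )
  ))
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    # problems() rows are file lines (header included)
    abort(sprintf("parse error at line %d: expected %s, got \"%s\"",
                  probs$row[1], probs$expected[1], probs$actual[1]))
  }
  validate_trial_log(trials, session = session, line_offset = 1)
  trials
}
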