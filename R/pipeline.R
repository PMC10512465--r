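#' Experiment plans: simulate, fit, and compare conditions
#'
#' An experiment plan bundles everything needed to rerun one of the study
#' designs end to end: cohort size, per-condition session configuration and
#' observer parameters, permutation settings and a master seed. Three named
#' presets ship with the package, their generative coefficients set to the
#' group-level estimates they are meant to reproduce qualitatively:
#'
#' * `"exp1"` — one condition, 17 participants, high density for both
#'   displays; baseline coefficients (center bias ~0.78/0.77, serial pull
#'   ~0.0094/0.010).
#' * `"exp2_form_density"` — two conditions, 18 participants each, varying
#'   the *form* display's density with the motion display fixed at high.
#' * `"exp2_motion_density"` — two conditions, 18 participants each,
#'   varying the *motion* display's density with the form display fixed at
#'   high. This is the design in which the serial pull of form on motion
#'   (`b_pre_other` of the motion equation) differs between conditions
#'   (0.024 low vs 0.0091 high), the asymmetry signature.
#'
#' @param experiment One of `"exp1"`, `"exp2_form_density"`,
#'   `"exp2_motion_density"`, `"custom"`.
#' @param n_participants Cohort size per condition (defaults to the preset's).
#' @param conditions For `"custom"`: a named list of conditions, each a list
#'   with elements `config` ([session_config()]) and `params`
#'   ([observer_params()]).
#' @param n_iter Permutation iterations for two-condition plans.
#' @param seed Master seed driving all stages.
#' @return An object of class `experiment_plan`.
#' @export
#' @examples
#' experiment_plan("exp1", seed = 1)
experiment_plan <- function(experiment = c("exp1", "exp2_form_density",
                                           "exp2_motion_density", "custom"),
                            n_participants = NULL, conditions = NULL,
                            n_iter = 10000, seed = 1) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    n_participants <- n_participants %||% 17L
    conditions <- list(
      baseline = list(config = session_config(), params = observer_params())
    )
  } else if (experiment == "exp2_form_density") {
    n_participants <- n_participants %||% 18L
    conditions <- list(
      low = list(
        config = session_config(form_density = "low"),
        params = observer_params(b_curr_fl = 0.71, b_pre_fm = 0.011,
                                b_curr_fm = 0.71, b_pre_fl = 0.0070)
      ),
      high = list(
        config = session_config(form_density = "high"),
        params = observer_params(b_curr_fl = 0.73, b_pre_fm = 0.012,
                                b_curr_fm = 0.78, b_pre_fl = 0.011)
      )
    )
  } else if (experiment == "exp2_motion_density") {
    n_participants <- n_participants %||% 18L
    conditions <- list(
      low = list(
        config = session_config(motion_density = "low"),
        params = observer_params(b_curr_fl = 0.65, b_pre_fm = 0.024,
                                b_curr_fm = 0.74, b_pre_fl = 0.016)
      ),
      high = list(
        config = session_config(motion_density = "high"),
        params = observer_params(b_curr_fl = 0.71, b_pre_fm = 0.0091,
                                b_curr_fm = 0.72, b_pre_fl = 0.015)
      )
    )
  } else {
    if (is.null(conditions) || is.null(names(conditions))) {
      abort("custom plans need a named `conditions` list")
    }
    n_participants <- n_participants %||% 17L
    for (cond in conditions) {
      stopifnot(inherits(cond$config, "session_config"),
                inherits(cond$params, "observer_params"))
    }
  }
  if (length(conditions) == 2) {
    # two-condition plans must differ only in density labels / observer params
    c1 <- conditions[[1]]$config; c2 <- conditions[[2]]$config
    same <- identical(c1[setdiff(names(c1), c("form_density", "motion_density"))],
                      c2[setdiff(names(c2), c("form_density", "motion_density"))])
    if (!same) abort("two-condition plans must share the session structure")
  }
  structure(
    list(experiment = experiment,
         n_participants = as.integer(n_participants),
         conditions = conditions,
         n_iter = as.integer(n_iter), seed = as.integer(seed)),
    class = "experiment_plan"
  )
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %s: %d condition(s) x %d participants, seed %d\n",
              x$experiment, length(x$conditions), x$n_participants, x$seed))
  invisible(x)
}

#' Serialize / restore an experiment plan
#'
#' Round-trippable JSON representation: a plan written and reloaded reruns
#' identically.
#'
#' @param plan An [experiment_plan()].
#' @param path Destination / source `.json` path.
#' @return `write_plan()`: `path`, invisibly. `read_plan()`: the plan.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "experiment_plan"))
  x <- unclass(plan)
  x$conditions <- lapply(x$conditions, function(cond) {
    list(config = unclass(cond$config), params = unclass(cond$params))
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  conditions <- lapply(x$conditions, function(cond) {
    list(config = do.call(session_config, cond$config),
         params = do.call(observer_params, cond$params))
  })
  experiment_plan(x$experiment, n_participants = x$n_participants,
                  conditions = if (x$experiment == "custom") conditions else NULL,
                  n_iter = x$n_iter, seed = x$seed) |>
    (function(p) { p$conditions <- conditions; p })()
}

#' Run an experiment plan end to end
#'
#' Simulates one cohort per condition, fits both trial-history equations
#' per condition, and — for two-condition plans — runs the permutation
#' comparison for the current and previous-other coefficients of both
#' equations. If `out_dir` is given, writes per-condition trial logs,
#' coefficient tables (text and CSV), the permutation table, a
#' machine-readable JSON summary, and a run log with seeds and timings.
#' The same plan and seed give a byte-identical bundle (timestamps live
#' only in the run log).
#'
#' @param plan An [experiment_plan()].
#' @param out_dir Optional output directory, created if needed.
#' @return A list of class `experiment_result`: `plan`, `trials` (named by
#'   condition), `fits` (tibble-indexed list), `fit_table`,
#'   `comparison` (`NULL` for one-condition plans), `interpretation`.
#' @export
run_experiment <- function(plan, out_dir = NULL) {
  stopifnot(inherits(plan, "experiment_plan"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("plan: %s, seed %d", plan$experiment, plan$seed))
  set.seed(plan$seed)
  cond_seeds <- sample.int(.Machine$integer.max, length(plan$conditions))
  perm_seed <- sample.int(.Machine$integer.max, 1)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }

  cond_names <- names(plan$conditions)
  trials <- stage("simulate", purrr::map2(
    plan$conditions, seq_along(plan$conditions),
    function(cond, i) {
      simulate_cohort(plan$n_participants, cond$config, cond$params,
                      seed = cond_seeds[i],
                      id_prefix = paste0(cond_names[i], "_p"))
    }
  ))
  log_lines <- c(log_lines,
                 sprintf("simulate: %s", paste(cond_names, collapse = ", ")),
                 sprintf("condition seeds: %s", paste(cond_seeds, collapse = ", ")))

  fits <- stage("fit", purrr::imap(trials, function(tr, cond) {
    list(
      eq1_motion = fit_serial_model(build_design_rows(tr, "motion"), "eq1_motion"),
      eq2_form = fit_serial_model(build_design_rows(tr, "form"), "eq2_form")
    )
  }))
  fit_table <- purrr::imap(fits, function(fl, cond) {
    dplyr::bind_rows(
      dplyr::mutate(tidy(fl$eq1_motion), equation = "eq1_motion"),
      dplyr::mutate(tidy(fl$eq2_form), equation = "eq2_form")
    ) |> dplyr::mutate(condition = cond, .before = 1)
  }) |> dplyr::bind_rows()

  interpretation <- purrr::imap(fits, function(fl, cond) {
    dplyr::bind_rows(interpret_fit(fl$eq1_motion), interpret_fit(fl$eq2_form)) |>
      dplyr::mutate(condition = cond, .before = 1)
  }) |> dplyr::bind_rows()

  comparison <- NULL
  if (length(trials) == 2) {
    comparison <- stage("permute", compare_conditions_report(
      trials[[1]], trials[[2]], n_iter = plan$n_iter, seed = perm_seed))
    log_lines <- c(log_lines, sprintf("permute: %d iterations, seed %d",
                                      plan$n_iter, perm_seed))
  }

  result <- structure(
    list(plan = plan, trials = trials, fits = fits, fit_table = fit_table,
         comparison = comparison, interpretation = interpretation),
    class = "experiment_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write", {
      for (cond in cond_names) {
        write_trial_log(trials[[cond]],
                        file.path(out_dir, paste0("trials_", cond, ".csv")))
      }
      render_tables(fit_table, comparison, out_dir)
      summary_list <- list(
        experiment = plan$experiment, seed = plan$seed,
        n_participants = plan$n_participants,
        fit_table = fit_table, comparison = comparison,
        interpretation = interpretation
      )
      jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
      writeLines(c(log_lines,
                   sprintf("package version: %s",
                           as.character(utils::packageVersion("serialfoe"))),
                   sprintf("finished: %s (%.1f s)", format(Sys.time()), elapsed)),
                 file.path(out_dir, "run_log.txt"))
    })
  }
  result
}

#' @export
print.experiment_result <- function(x, digits = 3, ...) {
  cat(sprintf("<experiment_result> %s\n", x$plan$experiment))
  df <- as.data.frame(x$fit_table[, c("condition", "equation", "term",
                                      "estimate", "std_error", "conf_low",
                                      "conf_high", "stars")])
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\npermutation comparison (low - high):\n")
    cmp <- as.data.frame(x$comparison)
    num <- vapply(cmp, is.numeric, logical(1))
    cmp[num] <- lapply(cmp[num], signif, digits = digits)
    print(cmp, row.names = FALSE)
  }
  invisible(x)
}

#' Write coefficient and permutation tables to disk
#'
#' Renders the pooled fit table in the report layout — one block per
#' condition and equation with rows b, SE, 95% CI and significance stars —
#' as aligned text, plus CSV copies of the raw tables. The stars legend
#' (* p<0.05, ** p<0.01, *** p<0.001) is footnoted.
#'
#' @param fit_table Tidy coefficient table as produced by
#'   [run_experiment()] (columns condition, equation, term, estimate,
#'   std_error, conf_low, conf_high, p_value, stars).
#' @param comparison Optional permutation comparison tibble.
#' @param destination Output directory.
#' @return Paths written, invisibly.
#' @export
render_tables <- function(fit_table, comparison = NULL, destination) {
  if (is.null(fit_table) || nrow(fit_table) == 0) {
    abort("no results to render")
  }
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  lines <- character()
  for (cond in unique(fit_table$condition)) {
    for (eq in unique(fit_table$equation)) {
      block <- fit_table[fit_table$condition == cond &
                           fit_table$equation == eq, ]
      if (nrow(block) == 0) next
      lines <- c(lines, sprintf("== condition: %s | equation: %s ==", cond, eq),
                 paste0("          ", paste(formatC(block$term, width = 12),
                                            collapse = "")))
      lines <- c(lines,
                 paste0("b         ", paste(formatC(
                   paste0(signif(block$estimate, 3), block$stars), width = 12),
                   collapse = "")),
                 paste0("SE        ", paste(formatC(
                   signif(block$std_error, 3), width = 12), collapse = "")),
                 paste0("95% CI lo ", paste(formatC(
                   signif(block$conf_low, 3), width = 12), collapse = "")),
                 paste0("95% CI hi ", paste(formatC(
                   signif(block$conf_high, 3), width = 12), collapse = "")),
                 "")
    }
  }
  lines <- c(lines, "* p < 0.05, ** p < 0.01, *** p < 0.001")
  txt <- file.path(destination, "fit_tables.txt")
  writeLines(lines, txt)
  paths <- c(paths, txt)
  csv <- file.path(destination, "fit_table.csv")
  readr::write_csv(fit_table, csv)
  paths <- c(paths, csv)

  if (!is.null(comparison) && nrow(comparison) > 0) {
    cmp_csv <- file.path(destination, "permutation_table.csv")
    readr::write_csv(comparison, cmp_csv)
    paths <- c(paths, cmp_csv)
  }
  invisible(paths)
}
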