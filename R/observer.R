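#' Generative parameters of the synthetic observer
#'
#' The observer reports, on each trial, a noisy linear read-out of the
#' current feature plus a small pull from the previous trial's
#' other-modality feature:
#' \deqn{\theta_{perceived} = b_{curr}\,\theta_{curr} +
#'       b_{pre}\,\theta_{prev\_other} + \varepsilon + N(0, \sigma^2).}
#' Motion trials use (`b_curr_fl`, `b_pre_fm`, `eps_fl`, `noise_sd_fl`):
#' the perceived motion direction depends on the current motion direction
#' and the previous form orientation. Form trials use the FM/FL mirror.
#' A `b_curr` below 1 produces center bias (compression toward 0 degrees);
#' a positive `b_pre` produces attractive serial dependence. The generative
#' dependence on the *next* trial is identically zero (causality) and is not
#' a parameter.
#'
#' Defaults are the group-level estimates of the high-density baseline
#' condition; the noise SD of 8 degrees is a calibration choice that puts
#' simulated coefficient standard errors at a 17-participant cohort near the
#' 0.004 scale of that condition's report.
#'
#' @param b_curr_fl,b_pre_fm Slopes for motion-trial responses (current
#'   motion direction; previous form orientation).
#' @param b_curr_fm,b_pre_fl Slopes for form-trial responses (current form
#'   orientation; previous motion direction).
#' @param eps_fl,eps_fm Constant terms, degrees.
#' @param noise_sd_fl,noise_sd_fm Response noise SD, degrees (>= 0).
#' @param pull_on_perceived If `TRUE` the serial pull acts on the previous
#'   trial's *perceived* value instead of its true feature. Off by default:
#'   the measurement model regresses on presented features, and the
#'   generator mirrors it.
#' @return An object of class `observer_params`.
#' @export
#' @examples
#' observer_params()                      # baseline preset
#' observer_params(b_curr_fl = 1, b_curr_fm = 1,
#'                 b_pre_fm = 0, b_pre_fl = 0,
#'                 noise_sd_fl = 0, noise_sd_fm = 0)  # identity observer
observer_params <- function(b_curr_fl = 0.78, b_pre_fm = 0.0094,
                            b_curr_fm = 0.77, b_pre_fl = 0.010,
                            eps_fl = 0, eps_fm = 0,
                            noise_sd_fl = 8, noise_sd_fm = 8,
                            pull_on_perceived = FALSE) {
  vals <- c(b_curr_fl, b_pre_fm, b_curr_fm, b_pre_fl, eps_fl, eps_fm)
  if (!all(is.finite(vals))) abort("observer slopes and constants must be finite")
  if (noise_sd_fl < 0 || noise_sd_fm < 0) abort("noise SDs must be >= 0")
  structure(
    list(b_curr_fl = b_curr_fl, b_pre_fm = b_pre_fm,
         b_curr_fm = b_curr_fm, b_pre_fl = b_pre_fl,
         eps_fl = eps_fl, eps_fm = eps_fm,
         noise_sd_fl = noise_sd_fl, noise_sd_fm = noise_sd_fm,
         pull_on_perceived = isTRUE(pull_on_perceived)),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  motion trials: b_curr = %g, b_pre(form) = %g, eps = %g, noise SD = %g deg\n",
              x$b_curr_fl, x$b_pre_fm, x$eps_fl, x$noise_sd_fl))
  cat(sprintf("  form trials:   b_curr = %g, b_pre(motion) = %g, eps = %g, noise SD = %g deg\n",
              x$b_curr_fm, x$b_pre_fl, x$eps_fm, x$noise_sd_fm))
  if (x$pull_on_perceived) cat("  serial pull acts on previous PERCEIVED value\n")
  invisible(x)
}

#' Simulate one perceptual response
#'
#' Draws a perceived angle for a single trial given the current feature and
#' (optionally) the previous trial's other-modality feature. Vectorized over
#' the angle arguments. Uses R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param modality `"form"` or `"motion"`; selects which parameter set of
#'   `params` applies.
#' @param theta_curr_deg Current trial's true feature angle, degrees.
#' @param theta_prev_other_deg Previous trial's other-modality feature angle,
#'   degrees, or `NA` for the first trial of a session (the term is omitted).
#' @param params An [observer_params()].
#' @return Perceived angle(s) in degrees.
#' @export
simulate_response <- function(modality, theta_curr_deg,
                              theta_prev_other_deg = NA_real_,
                              params = observer_params()) {
  modality <- match.arg(modality, MODALITIES)
  if (modality == "motion") {
    b_curr <- params$b_curr_fl; b_pre <- params$b_pre_fm
    eps <- params$eps_fl; sd_noise <- params$noise_sd_fl
  } else {
    b_curr <- params$b_curr_fm; b_pre <- params$b_pre_fl
    eps <- params$eps_fm; sd_noise <- params$noise_sd_fm
  }
  pre_term <- ifelse(is.na(theta_prev_other_deg), 0,
                     b_pre * theta_prev_other_deg)
  n <- max(length(theta_curr_deg), length(theta_prev_other_deg))
  b_curr * theta_curr_deg + pre_term + eps + rnorm(n, 0, sd_noise)
}

#' Simulate one alternating form/motion session
#'
#' Trials strictly alternate modality starting with `config$start_modality`;
#' every trial's true FoE angle is drawn independently and uniformly from
#' the configured grid; responses come from [simulate_response()] with the
#' previous trial's feature (the other modality, by alternation) as the
#' serial predictor. Trial 1 has no predecessor and its serial term is
#' omitted.
#'
#' @param config A [session_config()].
#' @param params An [observer_params()].
#' @param participant_id Identifier written into every record.
#' @param seed Optional integer seed; same seed, same session.
#' @return A trial-log tibble (columns `participant_id`, `trial_index`,
#'   `modality`, `density`, `true_foe_deg`, `perceived_foe_deg`).
#' @export
#' @examples
#' trials <- simulate_session(session_config(), seed = 1)
#' nrow(trials)          # 1320
#' table(trials$modality)
simulate_session <- function(config = session_config(),
                             params = observer_params(),
                             participant_id = "p1",
                             seed = NULL) {
  stopifnot(inherits(config, "session_config"),
            inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * config$n_trials_per_modality
  modality <- rep_len(c(config$start_modality,
                        other_modality(config$start_modality)), n)
  grid <- foe_grid(config)
  true_foe <- sample(grid, n, replace = TRUE)
  density <- ifelse(modality == "form", config$form_density,
                    config$motion_density)
  is_motion <- modality == "motion"
  b_curr <- ifelse(is_motion, params$b_curr_fl, params$b_curr_fm)
  b_pre <- ifelse(is_motion, params$b_pre_fm, params$b_pre_fl)
  eps <- ifelse(is_motion, params$eps_fl, params$eps_fm)
  sd_noise <- ifelse(is_motion, params$noise_sd_fl, params$noise_sd_fm)
  noise <- rnorm(n, 0, sd_noise)
  if (params$pull_on_perceived) {
    # sequential: each response feeds the next trial's serial term
    perceived <- numeric(n)
    prev_feature <- NA_real_
    for (i in seq_len(n)) {
      pre_term <- if (is.na(prev_feature)) 0 else b_pre[i] * prev_feature
      perceived[i] <- b_curr[i] * true_foe[i] + pre_term + eps[i] + noise[i]
      prev_feature <- perceived[i]
    }
  } else {
    prev_true <- c(NA_real_, true_foe[-n])
    pre_term <- ifelse(is.na(prev_true), 0, b_pre * prev_true)
    perceived <- b_curr * true_foe + pre_term + eps + noise
  }
  tibble::tibble(
    participant_id = participant_id,
    trial_index = seq_len(n),
    modality = modality,
    density = density,
    true_foe_deg = true_foe,
    perceived_foe_deg = perceived
  )
}

#' Simulate a cohort of independent participants
#'
#' Each participant gets an independent sub-seed derived from the master
#' seed, so the cohort is reproducible as a whole and participants are
#' mutually independent.
#'
#' @param n_participants Number of participants (>= 1).
#' @param config A [session_config()] shared by all participants.
#' @param params An [observer_params()] shared by all participants.
#' @param seed Master seed.
#' @param id_prefix Participant ids are `<id_prefix><i>`, zero-padded.
#' @return One trial-log tibble with all participants stacked, sorted by
#'   (participant_id, trial_index).
#' @export
simulate_cohort <- function(n_participants, config = session_config(),
                            params = observer_params(),
                            seed = NULL, id_prefix = "p") {
  stopifnot(n_participants >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_participants)
  width <- nchar(as.character(n_participants))
  ids <- sprintf(paste0(id_prefix, "%0", width, "d"), seq_len(n_participants))
  purrr::map2(ids, sub_seeds, function(id, s) {
    simulate_session(config, params, participant_id = id, seed = s)
  }) |> dplyr::bind_rows()
}
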