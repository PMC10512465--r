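#' Build trial-history regression rows for one target modality
#'
#' For every target-modality trial that has both a previous and a next trial
#' (the other modality, by alternation), one design row is produced:
#' the response `y` (perceived angle), the current trial's true feature
#' `x_curr`, the previous trial's other-modality feature `x_pre_other`, and
#' the next trial's other-modality feature `x_next_other`. Trials at the
#' session boundaries lacking a neighbour are dropped: a default
#' 1,320-trial session yields 659 rows per modality. Trials ineligible for
#' one equation still contribute as neighbours to the other equation's rows.
#'
#' @param trials Trial-log tibble, one or more participants; each
#'   participant's trials must form a valid alternating session.
#' @param target_modality `"motion"` builds rows for the motion-direction
#'   equation; `"form"` for the form-orientation equation.
#' @return A tibble with columns `participant_id`, `trial_index`, `density`
#'   (of the target trial), `y`, `x_curr`, `x_pre_other`, `x_next_other`,
#'   ordered by (participant_id, trial_index).
#' @export
#' @examples
#' trials <- simulate_session(session_config(), seed = 1)
#' rows <- build_design_rows(trials, "motion")
#' nrow(rows)  # 659
build_design_rows <- function(trials, target_modality = c("motion", "form")) {
  target_modality <- match.arg(target_modality)
  trials <- validate_trial_log(trials, session = TRUE)
  if (nrow(trials) == 0) {
    return(tibble::tibble(participant_id = character(), trial_index = integer(),
                          density = character(), y = double(),
                          x_curr = double(), x_pre_other = double(),
                          x_next_other = double()))
  }
  trials |>
    dplyr::arrange(.data$participant_id, .data$trial_index) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      x_pre_other = dplyr::lag(.data$true_foe_deg),
      x_next_other = dplyr::lead(.data$true_foe_deg)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$modality == target_modality,
                  !is.na(.data$x_pre_other), !is.na(.data$x_next_other)) |>
    dplyr::transmute(
      .data$participant_id, .data$trial_index, .data$density,
      y = .data$perceived_foe_deg, x_curr = .data$true_foe_deg,
      .data$x_pre_other, .data$x_next_other
    )
}

serial_terms <- c("b_curr", "b_pre_other", "b_next_other", "eps")

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Fit the multi-factor trial-history regression
#'
#' Ordinary least squares of the perceived angle on the current stimulus
#' angle, the previous other-modality angle and the next other-modality
#' angle, with a free intercept:
#' \deqn{\hat\theta = b_{curr}\,\theta_{curr} + b_{pre}\,\theta_{pre}
#'       + b_{next}\,\theta_{next} + \varepsilon.}
#' A `b_curr` whose 95% CI lies below 1 indicates center bias; a significant
#' positive (negative) `b_pre_other` indicates attractive (repulsive) serial
#' dependence; `b_next_other` is a causality control and should be null.
#' Standard errors come from the residual variance at `n - 4` degrees of
#' freedom; 95% CIs use the Student-t critical value at that df; p-values
#' are two-sided t tests. Rows from all participants are pooled into one
#' group-level fit; pass a single participant's rows for a per-participant
#' diagnostic fit.
#'
#' @param rows Design rows from [build_design_rows()] (at least 5).
#' @param equation Label for the fitted equation: `"eq1_motion"` (perceived
#'   motion direction) or `"eq2_form"` (perceived form orientation).
#' @return An object of class `serial_fit`: `coefficients` tibble (term,
#'   estimate, std_error, conf_low, conf_high, statistic, p_value, stars),
#'   `n_rows`, `df_residual`, `residual_sd` (deg), `r_squared`, `fitted`,
#'   `residuals`, and the `lm` object as `model`.
#' @export
#' @examples
#' trials <- simulate_session(session_config(), seed = 1)
#' fit <- fit_serial_model(build_design_rows(trials, "motion"), "eq1_motion")
#' fit
#' tidy(fit)
fit_serial_model <- function(rows, equation = c("eq1_motion", "eq2_form")) {
  equation <- match.arg(equation)
  needed <- c("y", "x_curr", "x_pre_other", "x_next_other")
  if (!all(needed %in% names(rows))) {
    abort(paste("design rows need columns:", paste(needed, collapse = ", ")))
  }
  if (nrow(rows) < 5) {
    abort("at least 5 design rows are required (4 parameters + 1 residual df)")
  }
  model <- lm(y ~ x_curr + x_pre_other + x_next_other, data = rows)
  if (model$rank < 4) {
    abort("rank-deficient design: predictors are collinear")
  }
  df <- model$df.residual
  sm <- summary(model)
  ct <- sm$coefficients
  # reorder so the intercept (eps) comes last, as in the report layout
  ord <- c("x_curr", "x_pre_other", "x_next_other", "(Intercept)")
  ct <- ct[ord, , drop = FALSE]
  tcrit <- qt(0.975, df)
  est <- unname(ct[, "Estimate"])
  se <- unname(ct[, "Std. Error"])
  pv <- unname(ct[, "Pr(>|t|)"])
  coefs <- tibble::tibble(
    term = serial_terms,
    estimate = est,
    std_error = se,
    conf_low = est - tcrit * se,
    conf_high = est + tcrit * se,
    statistic = unname(ct[, "t value"]),
    p_value = pv,
    stars = significance_stars(pv)
  )
  structure(
    list(equation = equation, coefficients = coefs,
         n_rows = nrow(rows), df_residual = df,
         residual_sd = sm$sigma, r_squared = sm$r.squared,
         fitted = unname(model$fitted.values),
         residuals = unname(model$residuals),
         model = model),
    class = "serial_fit"
  )
}

#' @export
print.serial_fit <- function(x, digits = 3, ...) {
  label <- c(eq1_motion = "perceived motion direction",
             eq2_form = "perceived form orientation")[x$equation]
  cat(sprintf("<serial_fit> %s (%s), n = %d rows, residual SD = %.3g deg\n",
              x$equation, label, x$n_rows, x$residual_sd))
  df <- as.data.frame(x$coefficients)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract one coefficient estimate from a serial fit
#' @param fit A `serial_fit`.
#' @param term One of `"b_curr"`, `"b_pre_other"`, `"b_next_other"`, `"eps"`.
#' @return The point estimate.
#' @export
coef_estimate <- function(fit, term) {
  stopifnot(inherits(fit, "serial_fit"))
  term <- match.arg(term, serial_terms)
  fit$coefficients$estimate[fit$coefficients$term == term]
}

#' Interpret a fitted trial-history regression
#'
#' Applies the sign and significance conventions of the analysis:
#' center bias is present when the `b_curr` CI upper bound is below 1;
#' serial dependence is attractive (repulsive) when `b_pre_other` is
#' positive (negative) and significant at 0.05, absent otherwise; the fit
#' is "sane" when the causality control `b_next_other` is not significant.
#'
#' @param fit A `serial_fit`.
#' @param alpha Significance level for the serial and next-trial terms.
#' @return A one-row tibble: `equation`, `center_bias` (logical),
#'   `serial_dependence` (`"attractive"`, `"repulsive"`, `"absent"`),
#'   `next_trial_null` (logical).
#' @export
interpret_fit <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "serial_fit"))
  co <- fit$coefficients
  row <- function(term) co[co$term == term, ]
  b_curr <- row("b_curr"); b_pre <- row("b_pre_other"); b_next <- row("b_next_other")
  # NaN p-values (zero-residual fits) count as non-significant
  serial <- if (isTRUE(b_pre$p_value < alpha)) {
    if (b_pre$estimate > 0) "attractive" else "repulsive"
  } else "absent"
  tibble::tibble(
    equation = fit$equation,
    center_bias = b_curr$conf_high < 1,
    serial_dependence = serial,
    next_trial_null = !isTRUE(b_next$p_value < alpha)
  )
}

#' @rdname fit_serial_model
#' @param x A `serial_fit`.
#' @param ... Unused.
#' @export
tidy.serial_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_serial_model
#' @export
glance.serial_fit <- function(x, ...) {
  tibble::tibble(
    equation = x$equation, n_rows = x$n_rows,
    df_residual = x$df_residual, residual_sd = x$residual_sd,
    r_squared = x$r_squared
  )
}

#' Coefficient plot for a serial fit
#'
#' Point estimates with 95% CIs for the three slope terms (the intercept is
#' on a different scale and is omitted). Reference lines mark 0 (no effect)
#' and, for `b_curr`, 1 (veridical perception).
#'
#' @param object A `serial_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.serial_fit <- function(object, ...) {
  co <- object$coefficients[object$coefficients$term != "eps", ]
  co$term <- factor(co$term, levels = c("b_curr", "b_pre_other", "b_next_other"))
  ggplot2::ggplot(co, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf_low,
                                          ymax = .data$conf_high)) +
    ggplot2::labs(x = NULL, y = "slope (95% CI)",
                  title = paste("Trial-history regression:", object$equation)) +
    ggplot2::theme_minimal()
}

#' Diagnostic scatter of responses against a predictor
#'
#' Bin-averaged perceived angle against the current (or previous
#' other-modality) true angle, with the marginal OLS line. The current-
#' stimulus panel visualizes center bias (slope < 1); the previous-stimulus
#' panel visualizes serial dependence (nonzero slope).
#'
#' @param rows Design rows from [build_design_rows()].
#' @param predictor `"x_curr"` or `"x_pre_other"`.
#' @param bin_deg Bin width in degrees for the averaged points.
#' @return A ggplot object.
#' @export
plot_response_bias <- function(rows, predictor = c("x_curr", "x_pre_other"),
                               bin_deg = 5) {
  predictor <- match.arg(predictor)
  binned <- rows |>
    dplyr::mutate(bin = round(.data[[predictor]] / bin_deg) * bin_deg) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_y = mean(.data$y), .groups = "drop")
  ref_slope <- if (predictor == "x_curr") 1 else 0
  ggplot2::ggplot(binned, ggplot2::aes(x = .data$bin, y = .data$mean_y)) +
    ggplot2::geom_abline(slope = ref_slope, intercept = 0,
                         colour = "grey60", linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::labs(x = paste(predictor, "(deg)"),
                  y = "mean perceived angle (deg)") +
    ggplot2::theme_minimal()
}
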