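test_that("design rows keep only target trials with both neighbours", {
  # 6-trial session F M F M F M: eligible motion trials are indices 2 and 4
  # (index 6 lacks a next form trial); eligible form trials are 3 and 5
  trials <- manual_trials(rep(c("form", "motion"), 3), c(10, 20, 30, 40, 50, 60),
                          perceived_deg = 1:6)
  motion_rows <- build_design_rows(trials, "motion")
  expect_equal(motion_rows$trial_index, c(2L, 4L))
  expect_equal(motion_rows$x_curr, c(20, 40))
  expect_equal(motion_rows$x_pre_other, c(10, 30))
  expect_equal(motion_rows$x_next_other, c(30, 50))
  expect_equal(motion_rows$y, c(2, 4))

  form_rows <- build_design_rows(trials, "form")
  expect_equal(form_rows$trial_index, c(3L, 5L))
  expect_equal(form_rows$x_pre_other, c(20, 40))

  # a default session yields 659 rows per modality (one boundary trial each)
  sess <- simulate_session(session_config(), seed = 2)
  expect_equal(nrow(build_design_rows(sess, "motion")), 659)
  expect_equal(nrow(build_design_rows(sess, "form")), 659)

  expect_equal(nrow(build_design_rows(manual_trials(character(), numeric()),
                                      "motion")), 0)
})

test_that("design rows require alternating sessions and name the culprit", {
  bad <- manual_trials(c("form", "form", "motion"), c(0, 1, 2), pid = "s9")
  expect_error(build_design_rows(bad, "motion"), "s9.*trial_index 2")
})

test_that("a perfect identity dataset fits exactly", {
  trials <- simulate_session(tiny_config(100), identity_params(), seed = 1)
  # a zero-residual fit makes summary.lm warn; the point of the test
  fit <- suppressWarnings(
    fit_serial_model(build_design_rows(trials, "motion"), "eq1_motion")
  )
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "b_curr"], 1, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "b_pre_other"], 0, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "b_next_other"], 0, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "eps"], 0, tolerance = 1e-8)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
})

test_that("fitted coefficients match the normal-equations oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    rows <- random_design_rows(50)
    fit <- fit_serial_model(rows)
    oracle <- ols_oracle(rows)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    expect_equal(est, oracle, tolerance = 1e-8)
  }

  # 6 hand-built rows, solved independently
  rows6 <- tibble::tibble(
    participant_id = "p", trial_index = 1:6, density = "high",
    x_curr = c(-30, -10, 0, 10, 25, 40),
    x_pre_other = c(5, -20, 15, -40, 30, 0),
    x_next_other = c(-15, 35, -5, 20, -25, 10),
    y = c(-24.1, -7.3, 1.2, 8.4, 19.9, 31.0)
  )
  fit6 <- fit_serial_model(rows6)
  est6 <- setNames(fit6$coefficients$estimate, fit6$coefficients$term)
  expect_equal(est6, ols_oracle(rows6), tolerance = 1e-8)
})

test_that("inference columns follow OLS theory at df = n - 4", {
  set.seed(3)
  rows <- random_design_rows(40)
  fit <- fit_serial_model(rows)
  expect_equal(fit$df_residual, 36)
  co <- tidy(fit)
  tcrit <- qt(0.975, 36)
  expect_equal(co$conf_low, co$estimate - tcrit * co$std_error)
  expect_equal(co$conf_high, co$estimate + tcrit * co$std_error)
  expect_equal(co$statistic, co$estimate / co$std_error)
  expect_equal(co$p_value, 2 * pt(-abs(co$statistic), 36))
  expect_true(all(co$conf_low < co$estimate & co$estimate < co$conf_high))
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))

  # residuals are orthogonal to every predictor column and sum with the
  # fitted values back to y
  expect_equal(fit$fitted + fit$residuals, rows$y)
  X <- cbind(1, rows$x_curr, rows$x_pre_other, rows$x_next_other)
  expect_equal(as.numeric(t(X) %*% fit$residuals), rep(0, 4),
               tolerance = 1e-9)
})

test_that("degenerate designs are refused", {
  set.seed(4)
  rows <- random_design_rows(10)
  expect_error(fit_serial_model(rows[1:4, ]), "at least 5")
  collinear <- rows
  collinear$x_next_other <- 2 * collinear$x_curr
  expect_error(fit_serial_model(collinear), "collinear")
})

test_that("estimates concentrate on the truth as n grows", {
  b_true <- c(b_curr = 0.8, b_pre_other = 0.015, b_next_other = 0)
  prev_se <- Inf
  for (n in c(500, 5000, 50000)) {
    set.seed(n)
    rows <- random_design_rows(n, b_curr = 0.8, b_pre = 0.015, noise_sd = 8)
    co <- tidy(fit_serial_model(rows))
    est <- setNames(co$estimate, co$term)[names(b_true)]
    se <- setNames(co$std_error, co$term)[names(b_true)]
    expect_true(all(abs(est - b_true) < 4 * se))
    expect_lt(max(se), prev_se)
    prev_se <- max(se)
  }
})

test_that("interpret_fit applies the sign and significance conventions", {
  set.seed(5)
  rows <- random_design_rows(20000, b_curr = 0.78, b_pre = 0.05,
                             noise_sd = 8)
  fit <- fit_serial_model(rows)
  out <- interpret_fit(fit)
  expect_true(out$center_bias)            # b_curr CI upper bound < 1
  expect_equal(out$serial_dependence, "attractive")
  expect_true(out$next_trial_null)

  rows_rep <- random_design_rows(20000, b_curr = 0.78, b_pre = -0.05,
                                 noise_sd = 8)
  expect_equal(interpret_fit(fit_serial_model(rows_rep))$serial_dependence,
               "repulsive")

  rows_null <- random_design_rows(200, b_curr = 1.2, b_pre = 0, noise_sd = 60)
  out_null <- interpret_fit(fit_serial_model(rows_null))
  expect_true(out_null$serial_dependence %in%
                c("absent", "attractive", "repulsive"))
})

test_that("tidy and glance return the documented shapes", {
  set.seed(6)
  fit <- fit_serial_model(random_design_rows(30), "eq2_form")
  co <- tidy(fit)
  expect_named(co, c("term", "estimate", "std_error", "conf_low",
                     "conf_high", "statistic", "p_value", "stars"))
  expect_equal(co$term, c("b_curr", "b_pre_other", "b_next_other", "eps"))
  gl <- glance(fit)
  expect_equal(gl$equation, "eq2_form")
  expect_equal(gl$n_rows, 30)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_response_bias(random_design_rows(100)), "ggplot")
})
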