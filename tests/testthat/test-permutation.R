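sim_condition_rows <- function(seed, n_participants = 2, n_per_modality = 100,
                               params = observer_params(), prefix = "p") {
  coh <- simulate_cohort(n_participants, session_config(n_per_modality),
                         params, seed = seed, id_prefix = prefix)
  build_design_rows(coh, "motion")
}

test_that("observed_difference equals the difference of per-condition fits", {
  set.seed(1)
  rows_a <- random_design_rows(60, b_pre = 0.03)
  rows_b <- random_design_rows(60, b_pre = 0.01)
  obs <- observed_difference(rows_a, rows_b, "b_pre_other")
  oracle <- ols_oracle(rows_a)["b_pre_other"] - ols_oracle(rows_b)["b_pre_other"]
  expect_equal(obs, unname(oracle), tolerance = 1e-8)

  # identical conditions give exactly zero
  expect_equal(observed_difference(rows_a, rows_a, "b_pre_other"), 0)
  expect_equal(observed_difference(rows_a, rows_a, "b_curr"), 0)

  expect_error(observed_difference(rows_a[1:3, ], rows_b), "low condition")
})

test_that("identical conditions give a p value near 1", {
  rows <- sim_condition_rows(seed = 2)
  pt <- permutation_test(rows, rows, "b_pre_other", n_iter = 200, seed = 1)
  expect_equal(pt$obs_diff, 0)
  expect_equal(pt$p_two_tailed, 1)  # every |null diff| >= 0
})

test_that("the permutation null is seed-deterministic", {
  low <- sim_condition_rows(seed = 3, prefix = "a")
  high <- sim_condition_rows(seed = 4, prefix = "b")
  p1 <- permutation_test(low, high, "b_pre_other", n_iter = 100, seed = 11)
  p2 <- permutation_test(low, high, "b_pre_other", n_iter = 100, seed = 11)
  expect_identical(p1$null_diffs, p2$null_diffs)
  expect_identical(p1$p_two_tailed, p2$p_two_tailed)
  p3 <- permutation_test(low, high, "b_pre_other", n_iter = 100, seed = 12)
  expect_false(identical(p1$null_diffs, p3$null_diffs))
  expect_length(p1$null_diffs, 100)
})

test_that("swapping the condition labels negates the statistic, same p", {
  low <- sim_condition_rows(seed = 5, prefix = "a",
                            params = observer_params(b_pre_fm = 0.04))
  high <- sim_condition_rows(seed = 6, prefix = "b")
  fwd <- permutation_test(low, high, "b_pre_other", n_iter = 100, seed = 21)
  rev <- permutation_test(high, low, "b_pre_other", n_iter = 100, seed = 21)
  expect_equal(rev$obs_diff, -fwd$obs_diff)
  expect_identical(rev$p_two_tailed, fwd$p_two_tailed)
  expect_identical(sort(abs(rev$null_diffs)), sort(abs(fwd$null_diffs)))
})

test_that("all shuffle strategies run; response-decoupling ones widen the null", {
  low <- sim_condition_rows(seed = 7, n_participants = 3, prefix = "a")
  high <- sim_condition_rows(seed = 8, n_participants = 3, prefix = "b")
  res <- lapply(c("serial", "all_columns", "joint", "none"), function(s) {
    permutation_test(low, high, "b_pre_other", n_iter = 100, seed = 1,
                     shuffle = s)
  })
  names(res) <- c("serial", "all_columns", "joint", "none")
  for (pt in res) expect_true(all(is.finite(pt$null_diffs)))
  expect_false(identical(res$serial$null_diffs, res$joint$null_diffs))
  # permuting the response away from x_curr inflates the pseudo-fit
  # residual variance, hence the null spread (the conservative variants)
  expect_gt(sd(res$all_columns$null_diffs), 1.5 * sd(res$serial$null_diffs))
  expect_gt(sd(res$joint$null_diffs), 1.5 * sd(res$serial$null_diffs))
  # the calibrated variants agree with the sampling scale of the statistic
  expect_equal(sd(res$serial$null_diffs), sd(res$none$null_diffs),
               tolerance = 0.3)
})

test_that("unequal condition sizes use the original split sizes", {
  low <- sim_condition_rows(seed = 9, n_participants = 1, prefix = "a")
  high <- sim_condition_rows(seed = 10, n_participants = 2, prefix = "b")
  pt <- permutation_test(low, high, "b_curr", n_iter = 20, seed = 2)
  expect_equal(pt$n_low, nrow(low))
  expect_equal(pt$n_high, nrow(high))
  expect_true(all(is.finite(pt$null_diffs)))
})

test_that("the test detects a large between-condition difference", {
  low <- sim_condition_rows(seed = 12, n_participants = 3, prefix = "a",
                            params = observer_params(b_curr_fl = 0.5))
  high <- sim_condition_rows(seed = 13, n_participants = 3, prefix = "b",
                             params = observer_params(b_curr_fl = 0.9))
  pt <- permutation_test(low, high, "b_curr", n_iter = 200, seed = 3)
  expect_lt(pt$p_two_tailed, 0.05)
  expect_lt(pt$obs_diff, 0)  # low minus high
})

test_that("tidy and autoplot summarize a permutation result", {
  low <- sim_condition_rows(seed = 14, prefix = "a")
  high <- sim_condition_rows(seed = 15, prefix = "b")
  pt <- permutation_test(low, high, "b_pre_other", n_iter = 50, seed = 4)
  td <- tidy(pt)
  expect_named(td, c("equation", "coefficient", "obs_diff", "p_two_tailed",
                     "n_iter", "null_mean", "null_sd", "null_q025",
                     "null_q975"))
  expect_s3_class(autoplot(pt), "ggplot")
  expect_output(print(pt), "two-tailed p")
})

test_that("compare_conditions_report covers both equations and coefficients", {
  cfg <- session_config(60)
  low <- simulate_cohort(2, cfg, observer_params(), seed = 31, id_prefix = "lo_p")
  high <- simulate_cohort(2, cfg, observer_params(), seed = 32, id_prefix = "hi_p")
  rep <- compare_conditions_report(low, high, n_iter = 50, seed = 5)
  expect_equal(nrow(rep), 4)
  expect_setequal(rep$equation, c("eq1_motion", "eq2_form"))
  expect_setequal(rep$coefficient, c("b_curr", "b_pre_other"))
  expect_true(all(rep$p_two_tailed >= 0 & rep$p_two_tailed <= 1))

  expect_error(compare_conditions_report(low[0, ], high), "both conditions")
})
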