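# Independent normal-equations OLS oracle: solve (X'X) b = X'y directly.
# Deliberately does not share code with fit_serial_model().
ols_oracle <- function(rows) {
  X <- cbind(1, rows$x_curr, rows$x_pre_other, rows$x_next_other)
  beta <- solve(t(X) %*% X, t(X) %*% rows$y)
  # order as (b_curr, b_pre_other, b_next_other, eps)
  c(b_curr = beta[2], b_pre_other = beta[3], b_next_other = beta[4],
    eps = beta[1])
}

# random full-rank design rows with known coefficients + noise
random_design_rows <- function(n, b_curr = 0.8, b_pre = 0.01, b_next = 0,
                               eps = 0, noise_sd = 5) {
  tibble::tibble(
    participant_id = "p1",
    trial_index = seq_len(n),
    density = "high",
    x_curr = runif(n, -45, 45),
    x_pre_other = runif(n, -45, 45),
    x_next_other = runif(n, -45, 45)
  ) |>
    dplyr::mutate(y = b_curr * x_curr + b_pre * x_pre_other +
                    b_next * x_next_other + eps + rnorm(n, 0, noise_sd))
}

identity_params <- function() {
  observer_params(b_curr_fl = 1, b_pre_fm = 0, b_curr_fm = 1, b_pre_fl = 0,
                  noise_sd_fl = 0, noise_sd_fm = 0)
}

# small session config for fast tests
tiny_config <- function(n_per_modality = 50, ...) {
  session_config(n_trials_per_modality = n_per_modality, ...)
}

# hand-rolled trial log with explicit values
manual_trials <- function(modality, true_deg, perceived_deg = true_deg,
                          pid = "p1", density = "high") {
  tibble::tibble(
    participant_id = pid,
    trial_index = seq_along(modality),
    modality = modality,
    density = density,
    true_foe_deg = true_deg,
    perceived_foe_deg = perceived_deg
  )
}
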