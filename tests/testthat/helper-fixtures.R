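# Shared fixtures: small profiles, trend models and cohorts built in code.

make_profile <- function(age = 42, sex = 0, line_freq = 60,
                         alpha_shift = 0, bump_scale = 1,
                         user_id = "U00001", n_sessions = 1L) {
  data.frame(user_id = user_id, age = age, sex = sex, line_freq = line_freq,
             n_sessions = n_sessions, alpha_shift = alpha_shift,
             bump_scale = bump_scale, stringsAsFactors = FALSE)
}

# trend without per-subject variability, for deterministic spectra
fixed_trend <- function(...) {
  spectral_trend_model(alpha_jitter_sd = 0, bump_scale_sdlog = 0, ...)
}

no_artifacts <- function() artifact_model(epoch_rate = 0)

# tiny config for fast end-to-end runs
small_config <- function(n_users = 8, seed = 11, ...) {
  cohort_config(n_users = n_users, sessions_per_user = c(1, 2),
                session_duration = c(CAL = 30, NFB = 30), seed = seed, ...)
}

# user-level design matrix of the age-trend model, for normal-equation oracles
trend_design <- function(age, sex, center_age = 42) {
  a <- age - center_age
  cbind(1, a, a^2, sex, a * sex, a^2 * sex)
}

# independent WLS/OLS oracle: solve the normal equations directly
ols_oracle <- function(age, sex, y, center_age = 42) {
  X <- trend_design(age, sex, center_age)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# independent single-window DFT oracle: naive O(n^2) sums, folded one-sided
dft_psd_oracle <- function(x) {
  n <- length(x)
  nyq <- n %/% 2
  p2 <- vapply(0:(n - 1), function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)))^2 / n^2
  }, numeric(1))
  c(p2[1], p2[2:nyq] + p2[n:(nyq + 2)], p2[nyq + 1])
}

# simulate a user-level cohort feature and return the data frame
simulated_cohort <- function(n, coefs, noise_sd, seed) {
  prof <- sample_cohort(cohort_config(n_users = n, seed = seed))
  prof$value <- simulate_user_features(prof, coefs, noise_sd)
  prof
}
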