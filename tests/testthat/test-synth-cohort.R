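test_that("sample_cohort respects size, range, sex balance and determinism", {
  expect_equal(nrow(sample_cohort(cohort_config(n_users = 0))), 0)

  cfg <- cohort_config(n_users = 10000, seed = 5)
  prof <- sample_cohort(cfg)
  expect_equal(nrow(prof), 10000)
  expect_true(all(prof$age >= 18 & prof$age <= 88))
  expect_true(all(prof$sex %in% 0:1))
  expect_true(all(prof$line_freq %in% c(50, 60)))
  # female fraction within 3 SE of the reference proportion
  p0 <- 1650 / 6029
  se <- sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(mean(prof$sex) - p0), 3 * se)

  expect_identical(prof, sample_cohort(cfg))
  expect_false(identical(prof$age, sample_cohort(cfg, seed = 6)$age))
})

test_that("config validation rejects bad ranges and probabilities", {
  expect_error(cohort_config(n_users = -1), "n_users")
  expect_error(cohort_config(age_range = c(10, 88)), "age_range")
  expect_error(cohort_config(age_range = c(60, 40)), "age_range")
  expect_error(cohort_config(p_female = 1.2), "p_female")
  expect_error(spectral_trend_model(alpha_bump_width = 0), "bump_width")
  expect_error(spectral_trend_model(background_scale = -1), ">= 0")
  expect_error(artifact_model(epoch_rate = 2), "epoch_rate")
})

test_that("alpha-bump centre follows the centred-age trend", {
  # no trend: same centre at any age
  flat <- fixed_trend(alpha_center_slope = 0, alpha_center_quad = 0)
  expect_identical(target_psd(make_profile(age = 20), flat, "TP10"),
                   target_psd(make_profile(age = 80), flat, "TP10"))

  # centring identity at age 42
  tr <- fixed_trend()
  expect_equal(eeglifespan:::alpha_center_at(tr, 42), 9.54145)
  # hand arithmetic: 9.54 - 0.0189 * (62 - 42) = 9.162
  tr2 <- fixed_trend(alpha_center_intercept = 9.54, alpha_center_slope = -0.0189)
  expect_equal(eeglifespan:::alpha_center_at(tr2, 62), 9.162)
  # and the integer-bin psd peaks at the nearest bin over a flat background
  psd <- target_psd(make_profile(age = 62), fixed_trend(
    alpha_center_intercept = 9.54, alpha_center_slope = -0.0189,
    background_scale = 0.01, alpha_bump_height = 5), "TP10")
  expect_equal(alpha_peak(psd), 9)

  # centre outside 8-13 Hz is a configuration error
  bad <- fixed_trend(alpha_center_intercept = 8.2, alpha_center_slope = -0.05)
  expect_error(target_psd(make_profile(age = 80), bad, "TP10"), "8-13")
})

test_that("target_psd scales by channel gain and sex offset", {
  tr <- fixed_trend()
  m <- make_profile(sex = 0); f <- make_profile(sex = 1)
  tp <- target_psd(m, tr, "TP10")
  af <- target_psd(m, tr, "AF8")
  expect_true(sum(tp[as.character(2:36)]) > sum(af[as.character(2:36)]))
  expect_equal(target_psd(f, tr, "TP10") / tp,
               rep(10^tr$sex_power_offset, 111), ignore_attr = TRUE)
  expect_error(target_psd(m, tr, "Cz"), "channel")
})

test_that("rendered sessions have the target spectrum and exact total power", {
  prof <- make_profile(age = 42)
  tr <- fixed_trend()
  ses <- render_session(prof, tr, no_artifacts(), duration = 300, seed = 21)
  expect_equal(dim(ses$samples), c(300 * 220, 4))

  # Parseval by construction: mean square equals the integral of the density
  n <- nrow(ses$samples); df <- 220 / n
  half <- floor((n - 1) / 2)
  for (ch in c("TP10", "AF7")) {
    dens <- eeglifespan:::target_density(prof, tr, ch, seq_len(half) * df)
    total <- sum(dens * df)
    if (n %% 2 == 0)
      total <- total + eeglifespan:::target_density(prof, tr, ch, 110) * df
    expect_equal(mean(ses$samples[, ch]^2), total, tolerance = 1e-10)
  }

  # Welch estimate matches the analytic target bin-wise in 2-36 Hz
  psd <- compute_psd(ses$samples, fs = 220)
  tgt <- target_psd(prof, tr, "TP10")
  bins <- as.character(2:36)
  rel <- abs(psd$power[bins, "TP10"] - tgt[bins]) / tgt[bins]
  expect_lt(max(rel), 0.20)
})

test_that("null spectrum renders an all-zero signal", {
  tr <- fixed_trend(background_scale = 0, alpha_bump_height = 0)
  ses <- render_session(make_profile(), tr, no_artifacts(), duration = 10, seed = 1)
  expect_equal(max(abs(ses$samples)), 0)
})

test_that("artifact injection matches the Bernoulli window rate", {
  prof <- make_profile()
  tr <- fixed_trend()
  art <- artifact_model(epoch_rate = 0.15)
  set.seed(31)
  n_win <- 0; n_bad <- 0
  for (i in 1:8) {
    ses <- render_session(prof, tr, art, duration = 120)
    n_win <- n_win + floor(nrow(ses$samples) / 256)
    n_bad <- n_bad + length(ses$artifact_windows)
  }
  se <- sqrt(0.15 * 0.85 / n_win)
  expect_lt(abs(n_bad / n_win - 0.15), 3 * se)
})

test_that("duration below 10 s is refused", {
  expect_error(render_session(make_profile(), fixed_trend(), duration = 5),
               "10 s")
})

test_that("write_cohort produces a readable, complete cohort", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_users = 3, seed = 9)
  prof <- sample_cohort(cfg)
  prof$n_sessions <- 2L
  man <- write_cohort(prof, cfg, fixed_trend(), no_artifacts(), dir)
  expect_equal(nrow(man), 3 * 2 * 2)  # users x sessions x tasks
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # round trip: stored precision is 1e-4 uV
  rt <- read_manifest(file.path(dir, "manifest.csv"))
  ses <- read_session(rt$sessions[1, ])
  set.seed(cfg$seed)  # write_cohort renders sequentially from its seed
  first <- render_session(prof[1, ], fixed_trend(), no_artifacts(),
                          duration = cfg$session_duration[["CAL"]],
                          task = "CAL", order = 1L)
  expect_equal(ses$samples, round(first$samples, 4), ignore_attr = TRUE)
})

test_that("feature-level simulator reproduces the generative mean structure", {
  prof <- data.frame(age = c(22, 42, 62), sex = c(0, 1, 0))
  coefs <- c(9.5, -0.02, 1e-4, 0.1, 0.001, -1e-5)
  set.seed(1)
  v <- simulate_user_features(prof, coefs, noise_sd = 0)
  a <- prof$age - 42
  expect_equal(v, coefs[1] + coefs[2] * a + coefs[3] * a^2 + coefs[4] * prof$sex +
                 coefs[5] * a * prof$sex + coefs[6] * a^2 * prof$sex)
})
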