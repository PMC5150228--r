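sinusoid <- function(f, dur = 10, fs = 220, amp = 1)
  amp * sin(2 * pi * f * seq(0, dur - 1 / fs, by = 1 / fs))

rms <- function(x) sqrt(mean(x^2))

# attenuation of a pure tone through a filter, in dB, edges trimmed
tone_db <- function(filter_fun, f, fs = 220) {
  x <- sinusoid(f, dur = 30, fs = fs)
  y <- filter_fun(x)
  i <- seq(2 * fs, length(x) - 2 * fs)
  20 * log10(rms(y[i]) / rms(x[i]))
}

test_that("notch filter removes the line frequency and spares the passband", {
  for (f0 in c(50, 60)) {
    nf <- function(x) notch_filter(x, fs = 220, line_freq = f0)
    expect_lt(tone_db(nf, f0), -20)          # >= 20 dB at the line frequency
    expect_gt(tone_db(nf, 10), -0.44)        # 10 Hz RMS preserved within 5%
    expect_gt(tone_db(nf, 36), -1)           # passband edge within 1 dB
    expect_equal(nf(rep(0, 2200)), rep(0, 2200), tolerance = 1e-12)
  }
  expect_error(notch_filter(sinusoid(10), fs = 220), "line_freq")
  expect_error(notch_filter(sinusoid(10), fs = 220, line_freq = 55), "50 or 60")
})

test_that("bandpass filter meets its attenuation contract", {
  bp <- function(x) bandpass_filter(x, fs = 220)
  expect_lt(tone_db(bp, 80), -20)
  expect_lt(tone_db(bp, 45), -20)
  for (f in c(5, 10, 20, 30)) expect_gt(tone_db(bp, f), -1)
  # constant offset is removed
  y <- bandpass_filter(rep(100, 4400), fs = 220)
  expect_lt(max(abs(y[seq(440, 3960)])), 1e-6)
})

test_that("epoch powers are mean squared amplitude over 256-sample windows", {
  # closed form: sinusoid of amplitude 2 with integer cycles -> a^2/2 = 2
  x <- 2 * sin(2 * pi * 8 * seq_len(256) / 256)
  expect_equal(epoch_powers(x, 256)[1, 1], 2)
  # constant 5 uV -> 25 uV^2
  expect_equal(epoch_powers(rep(5, 256), 256)[1, 1], 25)
  # all-zero epoch -> 0; 1024 samples -> 4 epochs; 255 samples -> none
  expect_equal(epoch_powers(rep(0, 256), 256)[1, 1], 0)
  expect_equal(nrow(epoch_powers(rnorm(1024), 256)), 4)
  expect_equal(nrow(epoch_powers(rnorm(255), 256)), 0)
})

test_that("epoch rejection is strict and joint across channels", {
  powers <- cbind(TP9 = c(274, 275, 276), AF7 = c(1, 1, 1),
                  AF8 = c(1, 1, 1), TP10 = c(1, 1, 1))
  r <- reject_epochs(powers, threshold = 275)
  expect_equal(r$keep, c(TRUE, TRUE, FALSE))
  # the epoch rejected on TP9 is dropped everywhere, but only TP9's
  # fraction reflects it
  expect_equal(unname(r$reject_frac), c(1 / 3, 0, 0, 0))
  expect_true(all(reject_epochs(matrix(0, 5, 4), 275)$keep))
})

test_that("session verdict uses a strict 10% rule and flags short sessions", {
  cfg <- preprocess_config()
  expect_equal(session_verdict(c(0.10, 0, 0, 0), n_kept = 90, cfg), "clean")
  expect_equal(session_verdict(c(0.101, 0, 0, 0), n_kept = 90, cfg),
               "rejected_artifacts")
  expect_equal(session_verdict(c(0, 0, 0, 0), n_kept = 90, cfg), "clean")
  expect_equal(session_verdict(c(0, 0, 0, 0), n_kept = 9, cfg), "too_short")
})

test_that("monotonicity: looser thresholds never reject more", {
  set.seed(4)
  powers <- matrix(rexp(400, rate = 1 / 150), 100, 4)
  kept <- vapply(c(100, 275, 500, 1000),
                 function(th) sum(reject_epochs(powers, th)$keep), numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("cap keeps the first five clean pairs and pairs CAL with NFB", {
  qc <- expand.grid(task = c("CAL", "NFB"), order = 1:8,
                    stringsAsFactors = FALSE)
  qc$user_id <- "U1"
  qc$verdict <- "clean"
  capped <- cap_sessions(qc, 5)
  expect_equal(sort(unique(qc$order[capped$retained])), 1:5)
  expect_equal(sum(capped$retained), 10)  # 5 per task

  # clean sessions 2, 5, 7 of 7 recorded: the cap counts clean ones
  qc2 <- expand.grid(task = c("CAL", "NFB"), order = 1:7,
                     stringsAsFactors = FALSE)
  qc2$user_id <- "U1"
  qc2$verdict <- ifelse(qc2$order %in% c(2, 5, 7), "clean", "rejected_artifacts")
  capped2 <- cap_sessions(qc2, 5)
  expect_equal(sort(unique(qc2$order[capped2$retained])), c(2, 5, 7))

  # a rejected NFB knocks out its CAL partner
  qc3 <- qc2[qc2$order %in% c(2, 5), ]
  qc3$verdict <- ifelse(qc3$order == 5 & qc3$task == "NFB",
                        "rejected_artifacts", "clean")
  capped3 <- cap_sessions(qc3, 5)
  expect_equal(unique(qc3$order[capped3$retained]), 2)
})

test_that("cleaning chain catches injected bursts and is idempotent", {
  prof <- make_profile(line_freq = 60)
  tr <- fixed_trend()
  ses <- render_session(prof, tr, artifact_model(epoch_rate = 0.08),
                        duration = 120, seed = 17)
  cs <- clean_session(ses)
  # every ground-truth-contaminated epoch is rejected (recall = 1 at this
  # amplitude); some collateral rejection at burst edges is allowed
  expect_true(all(!cs$keep[ses$artifact_windows]))
  expect_equal(cs$n_epochs, floor(nrow(ses$samples) / 256))

  # re-cleaning the already-clean signal rejects nothing
  again <- structure(list(samples = cs$samples, fs = cs$fs, task = cs$task,
                          order = cs$order, line_freq = 60,
                          user_id = cs$user_id, age = cs$age, sex = cs$sex),
                     class = "raw_session")
  cs2 <- clean_session(again)
  expect_true(all(cs2$keep))
  expect_equal(cs2$verdict, "clean")
})

test_that("preprocess_cohort accounts for every session and caps users", {
  dir <- withr::local_tempdir()
  cfg <- small_config(n_users = 4, seed = 23)
  prof <- sample_cohort(cfg)
  prof$n_sessions <- 7L  # force the cap to bite
  write_cohort(prof, cfg, fixed_trend(), no_artifacts(), dir)
  pre <- preprocess_cohort(file.path(dir, "manifest.csv"))
  expect_equal(nrow(pre$qc), 4 * 7 * 2)
  per_user <- table(pre$qc$user_id[pre$qc$retained & pre$qc$task == "NFB"])
  expect_true(all(per_user >= 1 & per_user <= 5))
  expect_equal(pre$n_rejected_sessions, 0)
})
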