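#' Configure a synthetic cohort
#'
#' Study-level parameters of the synthetic population: cohort size, age
#' range and per-age sampling weights, sex balance, sessions per user and
#' session durations. Defaults reproduce the reference study's conditions:
#' 6029 users aged 18-88 sampled with the decade-binned age distribution of
#' \code{\link{ref_age_distribution}}, a female fraction of 1650/6029, a
#' 1-minute calibration (CAL) recording and a 3-minute neurofeedback (NFB)
#' recording per session, sampled at 220 Hz.
#'
#' @param n_users number of users in the cohort.
#' @param age_range inclusive integer age bounds in years; minimum age 18.
#' @param p_female probability that a user is female (sex coded male = 0,
#'   female = 1).
#' @param age_weights optional per-age sampling weights (named by integer
#'   age, covering \code{age_range}); defaults to
#'   \code{\link{default_age_weights}}.
#' @param sessions_per_user integer range \code{c(min, max)} of recorded
#'   sessions per user (uniform).
#' @param session_duration named numeric vector, seconds of recording per
#'   task (\code{CAL}, \code{NFB}).
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer seed used by \code{\link{sample_cohort}} and
#'   \code{\link{write_cohort}} when no explicit seed is supplied.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_users = 6029L,
                          age_range = c(18L, 88L),
                          p_female = 1650 / 6029,
                          age_weights = NULL,
                          sessions_per_user = c(1L, 7L),
                          session_duration = c(CAL = 60, NFB = 180),
                          sampling_rate = 220,
                          seed = 1L) {
  if (n_users < 0) stop("n_users must be >= 0")
  if (length(age_range) != 2L || age_range[1] < 18 || age_range[1] > age_range[2])
    stop("age_range must satisfy 18 <= min <= max")
  if (p_female < 0 || p_female > 1) stop("p_female must be in [0, 1]")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(sessions_per_user) != 2L || sessions_per_user[1] < 1 ||
      sessions_per_user[1] > sessions_per_user[2])
    stop("sessions_per_user must be an increasing integer range with min >= 1")
  if (is.null(age_weights)) age_weights <- default_age_weights(age_range)
  ages <- seq(age_range[1], age_range[2])
  if (length(age_weights) != length(ages))
    stop("age_weights must have one entry per integer age in age_range")
  if (!all(c("CAL", "NFB") %in% names(session_duration)))
    stop("session_duration must name CAL and NFB durations")
  structure(list(
    n_users = as.integer(n_users), age_range = as.integer(age_range),
    p_female = p_female, age_weights = age_weights,
    sessions_per_user = as.integer(sessions_per_user),
    session_duration = session_duration,
    sampling_rate = sampling_rate, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Parametric population spectral model
#'
#' Generative model of a user's one-sided EEG power spectral density:
#' a 1/f^beta aperiodic background plus optional per-band plateaus and a
#' Gaussian alpha bump whose centre frequency follows a quadratic age trend
#' (centred at 42 years). The whole density is scaled per channel
#' (temporoparietal above frontal) and by sex (females above males).
#'
#' Defaults: the alpha-centre trend is the reference study's TP10
#' peak-frequency regression row (\code{\link{ref_trend_coefficients}}) -
#' 9.54145 Hz at age 42, slope -0.01891 Hz/year, no quadratic term. The
#' background and bump scales were chosen so synthetic log band powers land
#' near the reference intercept magnitudes; see the package vignette.
#' Per-user variability enters through \code{alpha_jitter_sd} (individual
#' deviation of the alpha centre, truncated so the bump stays inside
#' 8-13 Hz), \code{bump_scale_sdlog} (lognormal bump-height variability) and
#' \code{feature_noise} (residual SD used by the feature-level simulator
#' \code{\link{simulate_user_features}}).
#'
#' @param background_scale aperiodic power density at 1 Hz, uV^2/Hz.
#' @param background_exponent 1/f exponent beta (unitless).
#' @param band_plateaus named additive per-band power densities, uV^2/Hz.
#' @param alpha_center_intercept alpha-bump centre at age 42, Hz.
#' @param alpha_center_slope linear age trend of the centre, Hz/year.
#' @param alpha_center_quad quadratic age trend, Hz/year^2.
#' @param alpha_bump_height peak height of the Gaussian alpha bump, uV^2/Hz.
#' @param alpha_bump_width Gaussian sigma of the bump, Hz.
#' @param alpha_bump_channel_gain per-channel multiplier on the bump only;
#'   frontal channels get a weak bump so a realistic minority of frontal
#'   spectra show no detectable peak.
#' @param logpower_coeffs named list of 6-vectors (intercept, age, age^2,
#'   sex, age x sex, age^2 x sex on centred age), generative twins of the
#'   reference band-power regressions, used by
#'   \code{\link{simulate_user_features}}.
#' @param sex_power_offset female-minus-male offset of log10 power.
#' @param channel_gains per-channel multiplier on the whole density.
#' @param alpha_jitter_sd SD (Hz) of the per-user alpha-centre deviation.
#' @param bump_scale_sdlog lognormal sdlog of per-user bump height.
#' @param feature_noise named residual SDs for the feature-level simulator:
#'   \code{logpower} (log10 units) and \code{alpha_peak} (Hz).
#' @return a list of class \code{spectral_trend_model}.
#' @export
spectral_trend_model <- function(background_scale = 2,
                                 background_exponent = 1,
                                 band_plateaus = c(delta = 0, theta = 0, alpha = 0, beta = 0),
                                 alpha_center_intercept = 9.54145,
                                 alpha_center_slope = -0.01891,
                                 alpha_center_quad = 0,
                                 alpha_bump_height = 0.5,
                                 alpha_bump_width = 1.5,
                                 alpha_bump_channel_gain = c(TP9 = 1, AF7 = 0.25, AF8 = 0.25, TP10 = 1),
                                 logpower_coeffs = NULL,
                                 sex_power_offset = 0.05,
                                 channel_gains = c(TP9 = 1, AF7 = 0.35, AF8 = 0.35, TP10 = 1),
                                 alpha_jitter_sd = 0.75,
                                 bump_scale_sdlog = 0.5,
                                 feature_noise = c(logpower = 0.3, alpha_peak = 0.8)) {
  if (alpha_bump_width <= 0) stop("alpha_bump_width must be > 0")
  if (background_scale < 0 || alpha_bump_height < 0 || any(band_plateaus < 0) ||
      any(channel_gains < 0) || any(alpha_bump_channel_gain < 0))
    stop("all power parameters must be >= 0")
  if (is.null(logpower_coeffs)) {
    tab <- ref_trend_coefficients
    logpower_coeffs <- lapply(c("delta", "theta", "alpha", "beta"), function(m) {
      row <- tab[tab$measure == m & tab$channel == "TP10", ]
      c(intercept = row$intercept, age = row$age, age2 = row$age2,
        sex = row$sex, age_sex = row$age_sex, age2_sex = row$age2_sex)
    })
    names(logpower_coeffs) <- c("delta", "theta", "alpha", "beta")
  }
  structure(list(
    background_scale = background_scale, background_exponent = background_exponent,
    band_plateaus = band_plateaus,
    alpha_center_intercept = alpha_center_intercept,
    alpha_center_slope = alpha_center_slope, alpha_center_quad = alpha_center_quad,
    alpha_bump_height = alpha_bump_height, alpha_bump_width = alpha_bump_width,
    alpha_bump_channel_gain = alpha_bump_channel_gain,
    logpower_coeffs = logpower_coeffs,
    sex_power_offset = sex_power_offset, channel_gains = channel_gains,
    alpha_jitter_sd = alpha_jitter_sd, bump_scale_sdlog = bump_scale_sdlog,
    feature_noise = feature_noise
  ), class = "spectral_trend_model")
}

#' Configure synthetic artifact bursts
#'
#' High-amplitude bursts are injected into a Bernoulli subset of 256-sample
#' windows, on the same windows across all four channels (motion-like). The
#' default burst is an in-band 25 Hz sinusoid at 100 uV: its epoch power
#' (a^2/2 = 5000 uV^2) far exceeds the 275 uV^2 rejection threshold and
#' survives the 2-36 Hz band-pass, so ground-truth windows are recoverable
#' by the rejection stage.
#'
#' @param epoch_rate probability that a 256-sample window carries a burst.
#' @param burst_amplitude burst amplitude in uV.
#' @param burst_shape one of \code{"sinusoid"} (25 Hz), \code{"step"}
#'   (constant offset) or \code{"spike"} (single-sample impulse).
#' @return a list of class \code{artifact_model}.
#' @export
artifact_model <- function(epoch_rate = 0.05,
                           burst_amplitude = 100,
                           burst_shape = c("sinusoid", "step", "spike")) {
  if (epoch_rate < 0 || epoch_rate > 1) stop("epoch_rate must be in [0, 1]")
  if (burst_amplitude < 0) stop("burst_amplitude must be >= 0")
  burst_shape <- match.arg(burst_shape)
  structure(list(epoch_rate = epoch_rate, burst_amplitude = burst_amplitude,
                 burst_shape = burst_shape), class = "artifact_model")
}

# Alpha-bump centre for a given age (years), on the centred-age trend.
alpha_center_at <- function(trend, age, alpha_shift = 0) {
  a <- age - 42
  trend$alpha_center_intercept + trend$alpha_center_slope * a +
    trend$alpha_center_quad * a^2 + alpha_shift
}

#' Draw a cohort of subject profiles
#'
#' Samples \code{n_users} subjects: integer age from the configured per-age
#' weights, sex as Bernoulli(\code{p_female}) (male = 0, female = 1), line
#' frequency 50 or 60 Hz with equal probability, a uniform number of
#' recorded sessions, and the per-subject spectral individuality used by
#' \code{\link{target_psd}}: an alpha-centre deviation (normal with SD
#' \code{alpha_jitter_sd}, truncated so the bump centre stays inside
#' 8.25-12.75 Hz) and a lognormal bump-height scale.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param trend a \code{\link{spectral_trend_model}} supplying the
#'   individual-variability parameters.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return data frame with one row per subject: \code{user_id}, \code{age},
#'   \code{sex}, \code{line_freq}, \code{n_sessions}, \code{alpha_shift},
#'   \code{bump_scale}.
#' @export
sample_cohort <- function(config, trend = spectral_trend_model(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_users
  if (n == 0L) {
    return(data.frame(user_id = character(), age = integer(), sex = integer(),
                      line_freq = integer(), n_sessions = integer(),
                      alpha_shift = numeric(), bump_scale = numeric()))
  }
  ages <- seq(config$age_range[1], config$age_range[2])
  age <- sample(ages, n, replace = TRUE, prob = config$age_weights)
  sex <- stats::rbinom(n, 1L, config$p_female)
  line_freq <- sample(c(50L, 60L), n, replace = TRUE)
  n_sessions <- sample(seq(config$sessions_per_user[1], config$sessions_per_user[2]),
                       n, replace = TRUE)
  center <- alpha_center_at(trend, age)
  if (any(center < 8) || any(center > 13))
    stop("alpha centre leaves the 8-13 Hz band within age_range; adjust the trend model")
  shift <- stats::rnorm(n, 0, trend$alpha_jitter_sd)
  # keep each subject's bump centre inside the alpha band
  shift <- pmin(pmax(shift, 8.25 - center), 12.75 - center)
  bump_scale <- stats::rlnorm(n, 0, trend$bump_scale_sdlog)
  data.frame(user_id = sprintf("U%05d", seq_len(n)), age = age, sex = sex,
             line_freq = line_freq, n_sessions = n_sessions,
             alpha_shift = shift, bump_scale = bump_scale,
             stringsAsFactors = FALSE)
}

# One-sided target power spectral density (uV^2/Hz) at arbitrary
# frequencies. Below 1 Hz the aperiodic background is held at its 1 Hz
# value so low-frequency energy stays bounded; the density at 0 Hz is 0.
target_density <- function(profile, trend, channel, freqs) {
  if (!channel %in% eeg_channels) stop("unknown channel: ", channel)
  age <- profile$age
  shift <- if (!is.null(profile$alpha_shift)) profile$alpha_shift else 0
  bscale <- if (!is.null(profile$bump_scale)) profile$bump_scale else 1
  center0 <- alpha_center_at(trend, age)
  if (center0 < 8 || center0 > 13)
    stop("alpha centre ", round(center0, 3), " Hz outside 8-13 Hz at age ", age)
  center <- center0 + shift
  bg <- trend$background_scale * pmax(freqs, 1)^(-trend$background_exponent)
  bg[freqs == 0] <- 0
  plateau <- numeric(length(freqs))
  bands <- eeg_bands()
  for (b in names(trend$band_plateaus)) {
    i <- match(b, bands$name)
    sel <- freqs >= bands$lo[i] & freqs <= bands$hi[i]
    plateau[sel] <- plateau[sel] + trend$band_plateaus[[b]]
  }
  bump <- trend$alpha_bump_height * bscale * trend$alpha_bump_channel_gain[[channel]] *
    exp(-(freqs - center)^2 / (2 * trend$alpha_bump_width^2))
  gain <- trend$channel_gains[[channel]] * 10^(profile$sex * trend$sex_power_offset)
  gain * (bg + plateau + bump)
}

#' Target power spectrum of a subject at one channel
#'
#' Evaluates the generative spectral model at integer frequencies 0-110 Hz
#' (uV^2 per 1-Hz bin). This is the analytic oracle that rendered sessions
#' converge to; see \code{\link{render_session}}.
#'
#' @param profile one subject: a single row of \code{\link{sample_cohort}}
#'   output (or any list with \code{age}, \code{sex} and optionally
#'   \code{alpha_shift}, \code{bump_scale}).
#' @param trend a \code{\link{spectral_trend_model}}.
#' @param channel one of \code{"TP9"}, \code{"AF7"}, \code{"AF8"},
#'   \code{"TP10"}.
#' @return numeric vector of length 111 named by frequency, uV^2 per bin.
#' @export
target_psd <- function(profile, trend, channel) {
  f <- 0:110
  stats::setNames(target_density(profile, trend, channel, f), f)
}

#' Render one raw synthetic session
#'
#' Synthesizes a 4-channel time series whose expected spectrum equals the
#' subject's \code{\link{target_psd}}: deterministic spectral amplitudes
#' with i.i.d. uniform random phases (inverse FFT), giving a stationary
#' signal whose mean square power equals the integral of the target density
#' exactly. Artifact bursts are then added to a Bernoulli subset of
#' 256-sample windows (the same windows on all channels); the contaminated
#' window indices are kept as ground truth.
#'
#' @param profile one subject row (see \code{\link{target_psd}}).
#' @param trend a \code{\link{spectral_trend_model}}.
#' @param artifact an \code{\link{artifact_model}}.
#' @param duration seconds of signal; must be at least 10.
#' @param fs sampling rate, Hz.
#' @param task session task tag, \code{"CAL"} or \code{"NFB"}.
#' @param order session order for this user (1 = first).
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used (as when called from \code{\link{write_cohort}}).
#' @return a list of class \code{raw_session}: \code{samples} (n x 4 matrix,
#'   uV, columns in canonical channel order), \code{fs}, \code{task},
#'   \code{order}, \code{line_freq}, subject metadata, and
#'   \code{artifact_windows} (1-based indices of contaminated 256-sample
#'   windows).
#' @export
render_session <- function(profile, trend, artifact = artifact_model(),
                           duration, fs = 220, task = "NFB", order = 1L,
                           seed = NULL) {
  if (duration < 10) stop("duration must be >= 10 s")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  df <- fs / n
  half <- floor((n - 1) / 2)
  fk <- seq_len(half) * df
  samples <- matrix(0, n, length(eeg_channels),
                    dimnames = list(NULL, eeg_channels))
  for (ch in eeg_channels) {
    dens <- target_density(profile, trend, ch, fk)
    x_f <- complex(length.out = n)
    amp <- n * sqrt(dens * df / 2)
    phi <- stats::runif(half, 0, 2 * pi)
    x_f[1 + seq_len(half)] <- amp * exp(1i * phi)
    x_f[n + 1 - seq_len(half)] <- Conj(x_f[1 + seq_len(half)])
    if (n %% 2 == 0) {
      dens_nyq <- target_density(profile, trend, ch, fs / 2)
      x_f[n / 2 + 1] <- n * sqrt(dens_nyq * df) * sample(c(-1, 1), 1)
    }
    samples[, ch] <- Re(stats::fft(x_f, inverse = TRUE)) / n
  }
  n_win <- floor(n / 256)
  contaminated <- integer(0)
  if (n_win > 0 && artifact$epoch_rate > 0) {
    contaminated <- which(stats::runif(n_win) < artifact$epoch_rate)
    if (length(contaminated) > 0 && artifact$burst_amplitude > 0) {
      burst <- switch(artifact$burst_shape,
        sinusoid = artifact$burst_amplitude * sin(2 * pi * 25 * seq_len(256) / fs),
        step = rep(artifact$burst_amplitude, 256),
        spike = { b <- numeric(256); b[128] <- artifact$burst_amplitude; b })
      for (w in contaminated) {
        idx <- (w - 1L) * 256L + seq_len(256L)
        samples[idx, ] <- samples[idx, ] + burst
      }
    }
  }
  structure(list(samples = samples, fs = fs, task = task, order = as.integer(order),
                 line_freq = profile$line_freq, user_id = profile$user_id,
                 age = profile$age, sex = profile$sex,
                 artifact_windows = contaminated),
            class = "raw_session")
}

#' Render and write a whole cohort to disk
#'
#' For each subject, renders \code{n_sessions} CAL/NFB session pairs at the
#' configured durations and writes one CSV per session plus a cohort
#' manifest and an artifact ground-truth table. Output is bit-reproducible
#' given the same config, trend, artifact model and seed.
#'
#' @param profiles subject data frame from \code{\link{sample_cohort}}.
#' @param config the \code{\link{cohort_config}} (durations, sampling rate).
#' @param trend a \code{\link{spectral_trend_model}}.
#' @param artifact an \code{\link{artifact_model}}.
#' @param out_dir output directory (created if needed); session CSVs go to
#'   \code{out_dir/sessions/}.
#' @param seed integer seed; defaults to \code{config$seed}.
#' @return invisibly, the manifest data frame (also written to
#'   \code{out_dir/manifest.csv}); artifact ground truth is written to
#'   \code{out_dir/artifact_truth.csv} with one row per contaminated window.
#' @export
write_cohort <- function(profiles, config, trend = spectral_trend_model(),
                         artifact = artifact_model(), out_dir,
                         seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(file.path(out_dir, "sessions"), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  manifest <- list()
  truth <- list()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    for (ord in seq_len(prof$n_sessions)) {
      for (task in c("CAL", "NFB")) {
        ses <- render_session(prof, trend, artifact,
                              duration = config$session_duration[[task]],
                              fs = config$sampling_rate, task = task, order = ord)
        sid <- sprintf("%s_S%02d_%s", prof$user_id, ord, task)
        rel <- file.path("sessions", paste0(sid, ".csv"))
        write_session(ses, file.path(out_dir, rel))
        manifest[[sid]] <- data.frame(
          user_id = prof$user_id, session_id = sid, order = ord, task = task,
          age = prof$age, sex = prof$sex, line_freq = prof$line_freq,
          path = rel, stringsAsFactors = FALSE)
        if (length(ses$artifact_windows) > 0)
          truth[[sid]] <- data.frame(session_id = sid,
                                     window = ses$artifact_windows)
      }
    }
  }
  manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  if (is.null(manifest))
    manifest <- data.frame(user_id = character(), session_id = character(),
                           order = integer(), task = character(), age = integer(),
                           sex = integer(), line_freq = integer(), path = character())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  if (is.null(truth))
    truth <- data.frame(session_id = character(), window = integer())
  utils::write.csv(truth, file.path(out_dir, "artifact_truth.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Feature-level cohort simulator
#'
#' Draws per-user feature values directly from the generative regression
#' model: value = b0 + b1 a + b2 a^2 + b3 s + b4 a s + b5 a^2 s + noise,
#' with a = age - 42 (years) and s the sex code (male = 0, female = 1).
#' This is the fast statistical twin of the full render-preprocess-measure
#' pipeline, used for parameter-recovery and test-size simulations where
#' rendering raw signal for thousands of users is unnecessary.
#'
#' @param profiles subject data frame with \code{age} and \code{sex}.
#' @param coefs numeric length-6 coefficient vector (intercept, age, age^2,
#'   sex, age x sex, age^2 x sex on centred age).
#' @param noise_sd residual standard deviation.
#' @param center_age centring age in years.
#' @return numeric vector of simulated feature values, one per subject.
#' @export
simulate_user_features <- function(profiles, coefs, noise_sd, center_age = 42) {
  stopifnot(length(coefs) == 6L)
  a <- profiles$age - center_age
  s <- profiles$sex
  mu <- coefs[1] + coefs[2] * a + coefs[3] * a^2 + coefs[4] * s +
    coefs[5] * a * s + coefs[6] * a^2 * s
  mu + stats::rnorm(length(a), 0, noise_sd)
}
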