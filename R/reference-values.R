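#' Reference values from a large consumer-EEG population study
#'
#' Published summary numbers from a 6029-user study of four-channel consumer
#' EEG (TP9, AF7, AF8, TP10 at 220 Hz) recorded during a calibration task
#' (CAL) and a neurofeedback meditation period (NFB). The raw recordings are
#' proprietary; these printed summaries are the package's reference inputs:
#' they seed the synthetic-cohort defaults and support the arithmetic
#' identities recomputed by the acceptance script.
#'
#' \code{ref_session_accounting} gives the session bookkeeping of the study:
#' sessions recorded, sessions surviving artifact rejection, sessions
#' retained after the first-five-clean-sessions cap, and the user count.
#'
#' \code{ref_age_distribution} gives user counts by age decade and sex.
#'
#' \code{ref_alpha_peak_counts} gives, per task and channel, how many of the
#' 6029 users showed a detectable alpha peak.
#'
#' \code{ref_trend_coefficients} gives the study's NFB-condition regression
#' table: per measure and channel, the six weighted-least-squares
#' coefficients on centred age (intercept, age, age^2, sex, age x sex,
#' age^2 x sex) and the model R^2. The \code{alpha_peak} TP10 row supplies
#' the default generative alpha-centre trend of
#' \code{\link{spectral_trend_model}}.
#'
#' @format Lists and data frames; ages in years, peak frequencies in Hz,
#'   band powers in log10 microvolts-squared.
#' @name reference_values
NULL

#' @rdname reference_values
#' @export
ref_session_accounting <- list(
  sessions_recorded = 139548L,
  sessions_clean    = 74321L,
  sessions_retained = 22386L,
  n_users           = 6029L
)

#' @rdname reference_values
#' @export
ref_age_distribution <- data.frame(
  age_lo = c(18L, 20L, 30L, 40L, 50L, 60L, 70L, 80L),
  age_hi = c(19L, 29L, 39L, 49L, 59L, 69L, 79L, 88L),
  male   = c(48L, 854L, 1227L, 1059L, 708L, 400L, 77L, 6L),
  female = c(17L, 324L, 419L, 359L, 344L, 166L, 20L, 1L)
)

#' @rdname reference_values
#' @export
ref_alpha_peak_counts <- data.frame(
  task    = rep(c("NFB", "CAL"), each = 4),
  channel = rep(c("TP9", "TP10", "AF7", "AF8"), 2),
  n_peak  = c(5374L, 5379L, 3085L, 2806L, 5136L, 5320L, 3111L, 2939L)
)

#' @rdname reference_values
#' @export
ref_trend_coefficients <- local({
  rows <- rbind(
    c("delta", "AF7",   0.29099, -0.00202,  0.00013, -0.02249,  0.00133,  0.00011, 0.267),
    c("delta", "AF8",   0.28779, -0.00267,  0.00013, -0.02768,  0.00130,  0.00012, 0.319),
    c("delta", "TP9",   0.76347, -0.00388,  0.00011, -0.00821, -0.00021,  0.00006, 0.620),
    c("delta", "TP10",  0.74835, -0.00418,  0.00014,  0.00111,  0.00013,  0.00000, 0.662),
    c("theta", "AF7",  -0.24320, -0.00136,  0.00008,  0.02290,  0.00207,  0.00010, 0.412),
    c("theta", "AF8",  -0.26573, -0.00146,  0.00007,  0.00793,  0.00161,  0.00013, 0.365),
    c("theta", "TP9",   0.35367, -0.00196,  0.00004, -0.02996,  0.00082,  0.00014, 0.373),
    c("theta", "TP10",  0.31149, -0.00262,  0.00009, -0.00430,  0.00087,  0.00010, 0.480),
    c("alpha", "AF7",  -0.39869,  0.00123,  0.00007,  0.11474,  0.00206,  0.00008, 0.815),
    c("alpha", "AF8",  -0.44195,  0.00101,  0.00006,  0.08223,  0.00142,  0.00010, 0.712),
    c("alpha", "TP9",   0.48919,  0.00049, -0.00005, -0.02840,  0.00065,  0.00016, 0.105),
    c("alpha", "TP10",  0.47046,  0.00024, -0.00002, -0.00498,  0.00052,  0.00013, 0.087),
    c("beta",  "AF7",  -0.18422,  0.00197,  0.00011,  0.26647,  0.00174,  0.00004, 0.868),
    c("beta",  "AF8",  -0.23850,  0.00233,  0.00008,  0.21553,  0.00046,  0.00003, 0.813),
    c("beta",  "TP9",   0.29314,  0.00206, -0.00005,  0.05542,  0.00067,  0.00012, 0.669),
    c("beta",  "TP10",  0.28957,  0.00216,  0.00000,  0.08575,  0.00011,  0.00007, 0.675),
    c("alpha_peak", "AF7",  9.72796, -0.03847,  0.00052, -0.03651,  0.00159, -0.00028, 0.779),
    c("alpha_peak", "AF8",  9.82156, -0.03457,  0.00010, -0.05259, -0.00074, -0.00009, 0.665),
    c("alpha_peak", "TP9",  9.46783, -0.01795,  0.00001,  0.11219, -0.00647, -0.00032, 0.723),
    c("alpha_peak", "TP10", 9.54145, -0.01891,  0.00000,  0.06429, -0.00865,  0.00004, 0.768),
    c("alpha_asym", "AF8-AF7",  -0.04326, -0.00022,  0.00000, -0.03251, -0.00064,  0.00002, 0.235),
    c("alpha_asym", "TP10-TP9", -0.01873, -0.00025,  0.00004,  0.02342, -0.00013, -0.00003, 0.246)
  )
  out <- data.frame(
    measure   = rows[, 1],
    channel   = rows[, 2],
    intercept = as.numeric(rows[, 3]),
    age       = as.numeric(rows[, 4]),
    age2      = as.numeric(rows[, 5]),
    sex       = as.numeric(rows[, 6]),
    age_sex   = as.numeric(rows[, 7]),
    age2_sex  = as.numeric(rows[, 8]),
    r_squared = as.numeric(rows[, 9])
  )
  out
})

#' Default per-age sampling weights matching the reference age distribution
#'
#' Expands the decade-binned user counts of \code{ref_age_distribution} into
#' one weight per integer age (uniform within each decade bin), over a given
#' age range.
#'
#' @param age_range integer vector of length 2, inclusive age bounds in years.
#' @return named numeric vector of weights, one per integer age; weights sum
#'   to 1.
#' @export
default_age_weights <- function(age_range = c(18L, 88L)) {
  ages <- seq(age_range[1], age_range[2])
  w <- vapply(ages, function(a) {
    i <- which(ref_age_distribution$age_lo <= a & a <= ref_age_distribution$age_hi)
    if (length(i) != 1L) return(0)
    bin <- ref_age_distribution[i, ]
    (bin$male + bin$female) / (bin$age_hi - bin$age_lo + 1)
  }, numeric(1))
  if (sum(w) <= 0) stop("age_range does not overlap the reference age distribution")
  stats::setNames(w / sum(w), ages)
}
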