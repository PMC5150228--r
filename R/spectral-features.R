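#' 1-Hz power spectrum of a cleaned session
#'
#' Tiles the concatenated clean samples with non-overlapping rectangular
#' windows of \code{fs} samples (220 samples at 220 Hz, so the frequency
#' grid is exactly 1 Hz), averages the per-window periodograms, and folds
#' them one-sided onto integer frequencies 0-110 Hz. Powers are uV^2 per
#' 1-Hz bin and satisfy Parseval's identity: their sum equals the mean
#' squared amplitude of the analysed samples.
#'
#' @param x a \code{clean_session}, or a samples-by-channels matrix (uV).
#' @param fs sampling rate, Hz; must be a whole number of samples per
#'   second so the 1-Hz grid is exact.
#' @return a list of class \code{eeg_psd}: \code{power} (111-by-channels
#'   matrix, rows named by frequency), \code{freq} (0:110) and
#'   \code{n_windows}.
#' @export
compute_psd <- function(x, fs = 220) {
  if (inherits(x, "clean_session")) {
    if (!is.null(x$verdict) && x$verdict != "clean")
      stop("session verdict is '", x$verdict, "'; spectrum not computed")
    fs <- x$fs
    x <- x$samples
  }
  x <- as_sample_matrix(x)
  nwin_len <- as.integer(round(fs))
  if (abs(fs - nwin_len) > 1e-9) stop("fs must be an integer number of Hz")
  n_windows <- floor(nrow(x) / nwin_len)
  if (n_windows < 1)
    stop("too few clean samples for a spectrum (need at least ", nwin_len, ")")
  nyq <- nwin_len %/% 2L
  acc <- matrix(0, nyq + 1L, ncol(x))
  for (w in seq_len(n_windows)) {
    idx <- (w - 1L) * nwin_len + seq_len(nwin_len)
    for (ch in seq_len(ncol(x))) {
      p2 <- Mod(stats::fft(x[idx, ch]))^2 / nwin_len^2
      one <- c(p2[1], p2[2:nyq] + p2[nwin_len:(nyq + 2L)], p2[nyq + 1L])
      acc[, ch] <- acc[, ch] + one
    }
  }
  power <- acc / n_windows
  dimnames(power) <- list(0:nyq, colnames(x))
  structure(list(power = power, freq = 0:nyq, n_windows = n_windows),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d channel(s), 1-Hz bins 0-%d Hz, %d window(s)\n",
              ncol(x$power), max(x$freq), x$n_windows))
  invisible(x)
}

spectrum_vector <- function(psd, channel = NULL) {
  if (inherits(psd, "eeg_psd")) {
    if (is.null(channel)) {
      if (ncol(psd$power) != 1L) stop("channel is required for a multi-channel psd")
      channel <- 1L
    }
    return(stats::setNames(psd$power[, channel], rownames(psd$power)))
  }
  if (is.null(names(psd))) names(psd) <- seq_along(psd) - 1L
  psd
}

#' Band power and log band power
#'
#' Sum of spectral power over the integer bins \code{lo <= f <= hi}
#' (inclusive at both edges), and its log10. A band with zero power has no
#' defined log power and yields \code{NA} (feature absent) rather than
#' \code{-Inf}.
#'
#' @param psd an \code{eeg_psd} or a named numeric spectrum (uV^2 per bin).
#' @param band a band name from \code{\link{eeg_bands}} or numeric
#'   \code{c(lo, hi)}.
#' @param channel channel name, required for a multi-channel \code{eeg_psd}.
#' @return power in uV^2 (\code{band_power}) or log10 power
#'   (\code{log_band_power}).
#' @export
band_power <- function(psd, band, channel = NULL) {
  s <- spectrum_vector(psd, channel)
  b <- band_lookup(band)
  f <- as.numeric(names(s))
  sum(s[f >= b["lo"] & f <= b["hi"]])
}

#' @rdname band_power
#' @export
log_band_power <- function(psd, band, channel = NULL) {
  p <- band_power(psd, band, channel)
  if (p <= 0) return(NA_real_)
  log10(p)
}

#' Peak alpha frequency
#'
#' The frequency with maximal power in the 8-13 Hz range, reported only
#' when it is a strict local maximum of the full spectrum (its power
#' strictly exceeds both adjacent bins, so the 8 and 13 Hz candidates are
#' checked against 7 and 14 Hz). Ties are broken to the lowest frequency.
#' Monotonically decreasing 1/f-like spectra therefore yield no peak
#' (\code{NA}), mirroring how not every person shows a visible alpha peak.
#'
#' @inheritParams band_power
#' @return peak frequency in Hz, or \code{NA} when no peak is detectable.
#' @export
alpha_peak <- function(psd, channel = NULL) {
  s <- spectrum_vector(psd, channel)
  f <- as.numeric(names(s))
  cand <- which(f >= 8 & f <= 13)
  vals <- s[cand]
  m <- cand[which.max(vals)]  # which.max takes the lowest index on ties
  lo <- which(f == f[m] - 1)
  hi <- which(f == f[m] + 1)
  if (length(lo) != 1L || length(hi) != 1L)
    stop("spectrum must cover the neighbours 7 and 14 Hz")
  if (s[m] > s[lo] && s[m] > s[hi]) f[m] else NA_real_
}

#' Alpha asymmetry
#'
#' Right-minus-left difference of log10 alpha power: frontal asymmetry is
#' log10(alpha AF8) - log10(alpha AF7) and temporoparietal asymmetry is
#' log10(alpha TP10) - log10(alpha TP9). Negative values mean stronger left
#' than right alpha power. Absent (NA) if either side's log power is
#' absent.
#'
#' @param log_alpha named numeric vector of per-channel log10 alpha powers
#'   (names from \code{\link{eeg_channels}}).
#' @return named numeric vector with elements \code{frontal} and
#'   \code{temporoparietal}.
#' @export
alpha_asymmetry <- function(log_alpha) {
  c(frontal = unname(log_alpha["AF8"] - log_alpha["AF7"]),
    temporoparietal = unname(log_alpha["TP10"] - log_alpha["TP9"]))
}

#' Spectral features of one cleaned session
#'
#' Computes the 1-Hz spectrum and derives, per channel, the log10 band
#' powers for every canonical band and the peak alpha frequency, plus the
#' frontal and temporoparietal alpha asymmetries.
#'
#' @param cs a \code{clean_session} with verdict \code{"clean"}.
#' @return one-row data frame: metadata (\code{user_id}, \code{task},
#'   \code{order}, \code{age}, \code{sex}, \code{n_windows}) and columns
#'   \code{<channel>_<band>}, \code{<channel>_alpha_peak},
#'   \code{asym_frontal}, \code{asym_temporoparietal}.
#' @export
session_features <- function(cs) {
  psd <- compute_psd(cs)
  bands <- eeg_bands()$name
  out <- list(user_id = cs$user_id %||% NA_character_,
              task = cs$task %||% NA_character_,
              order = cs$order %||% NA_integer_,
              age = cs$age %||% NA_integer_, sex = cs$sex %||% NA_integer_,
              n_windows = psd$n_windows)
  log_alpha <- stats::setNames(rep(NA_real_, 4), eeg_channels)
  for (ch in eeg_channels) {
    for (b in bands) out[[paste(ch, b, sep = "_")]] <- log_band_power(psd, b, ch)
    out[[paste0(ch, "_alpha_peak")]] <- alpha_peak(psd, ch)
    log_alpha[ch] <- out[[paste(ch, "alpha", sep = "_")]]
  }
  asym <- alpha_asymmetry(log_alpha)
  out$asym_frontal <- asym[["frontal"]]
  out$asym_temporoparietal <- asym[["temporoparietal"]]
  as.data.frame(out, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average session features per user and task
#'
#' Arithmetic mean of each feature over a user's retained sessions of one
#' task (at most five), computed on the log scale for band powers
#' (transform-then-average). Peak alpha is averaged over the sessions where
#' a peak was present; the per-channel count of contributing sessions is
#' recorded so downstream regression weights can reflect it.
#'
#' @param rows data frame of \code{\link{session_features}} rows for one
#'   user and task.
#' @return one-row data frame with the averaged features, \code{n_sessions}
#'   and per-channel \code{n_peak_<channel>} counts.
#' @export
average_user_features <- function(rows) {
  stopifnot(nrow(rows) >= 1L)
  meta <- rows[1, c("user_id", "task", "age", "sex")]
  feat_cols <- setdiff(names(rows), c("user_id", "task", "order", "age", "sex",
                                      "n_windows"))
  means <- lapply(rows[feat_cols], function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  out <- cbind(meta, n_sessions = nrow(rows), as.data.frame(means))
  for (ch in eeg_channels)
    out[[paste0("n_peak_", ch)]] <- sum(!is.na(rows[[paste0(ch, "_alpha_peak")]]))
  out
}

#' Per-user feature table for a preprocessed cohort
#'
#' Computes session features for every retained cleaned session and
#' averages them per user and task.
#'
#' @param pre result of \code{\link{preprocess_cohort}}; when it was run
#'   with an \code{out_dir}, pass that directory as \code{dir} so the
#'   cleaned CSVs can be read back.
#' @param dir the preprocessing output directory (required when sessions
#'   are not held in memory).
#' @param out_file optional path to also write the table as CSV.
#' @return data frame with one row per user and task.
#' @export
features_table <- function(pre, dir = NULL, out_file = NULL) {
  qc <- pre$qc[pre$qc$retained, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(qc))) {
    sid <- qc$session_id[i]
    if (!is.null(pre$sessions)) {
      cs <- pre$sessions[[sid]]
    } else {
      if (is.null(dir)) stop("dir is required when cleaned sessions are on disk")
      raw <- read_session(file.path(dir, qc$clean_path[i]))
      cs <- structure(list(samples = raw$samples, fs = raw$fs, verdict = "clean",
                           task = qc$task[i], order = qc$order[i],
                           user_id = qc$user_id[i], age = qc$age[i],
                           sex = qc$sex[i]),
                      class = "clean_session")
    }
    rows[[sid]] <- session_features(cs)
  }
  rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- list()
  for (grp in split(seq_len(nrow(rows)), list(rows$user_id, rows$task), drop = TRUE))
    out[[length(out) + 1L]] <- average_user_features(rows[grp, , drop = FALSE])
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out <- out[order(out$user_id, out$task), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_file)) utils::write.csv(out, out_file, row.names = FALSE)
  out
}
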