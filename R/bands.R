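#' Canonical channel set
#'
#' The four recording channels in canonical order: left and right
#' temporoparietal (TP9, TP10) and left and right frontal (AF7, AF8).
#'
#' @export
eeg_channels <- c("TP9", "AF7", "AF8", "TP10")

#' Canonical frequency bands
#'
#' Integer-Hz band edges (inclusive at both ends): delta 0-2, theta 3-7,
#' alpha 8-13, beta 14-30 Hz, plus the lower (8-10) and upper (11-13) alpha
#' sub-bands and a broadband "total" 0-30 Hz range.
#'
#' @return data frame with columns \code{name}, \code{lo}, \code{hi} (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "lower_alpha", "upper_alpha", "total"),
    lo   = c(0L, 3L, 8L, 14L, 8L, 11L, 0L),
    hi   = c(2L, 7L, 13L, 30L, 10L, 13L, 30L)
  )
}

band_lookup <- function(band) {
  bands <- eeg_bands()
  if (is.character(band)) {
    i <- match(band, bands$name)
    if (is.na(i)) stop("unknown band: ", band)
    return(c(lo = bands$lo[i], hi = bands$hi[i]))
  }
  if (is.numeric(band) && length(band) == 2L) {
    if (band[1] < 0 || band[2] > 110 || band[1] > band[2])
      stop("band edges must satisfy 0 <= lo <= hi <= 110")
    return(c(lo = band[1], hi = band[2]))
  }
  stop("band must be a band name or a numeric c(lo, hi)")
}
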