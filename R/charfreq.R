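#' Characteristic (first-harmonic) frequency of a buzz spectrum
#'
#' Picks the bin-center frequency of the maximal magnitude within a search
#' band. The characteristic frequency of a flight buzz is its first harmonic
#' (fundamental), equal to the wing-beat frequency; for bumble bees it falls
#' between roughly 120 and 400 Hz, which is the default band.
#'
#' The caller is expected to pass a noise-subtracted, smoothed spectrum (see
#' \code{\link{power_spectrum}}, \code{\link{smooth_spectrum}}). Ties are
#' broken toward the lower frequency. An octave-error guard handles harmonic
#' series with a weak fundamental: if the magnitude at half the picked
#' frequency (when inside the band) exceeds \code{octave_ratio} times the
#' peak, the half frequency is reported instead.
#'
#' @param spectrum a \code{"buzz_spectrum"} (from \code{\link{power_spectrum}})
#'   or a numeric vector of per-bin magnitudes (then \code{bin_freqs} is
#'   required).
#' @param band numeric length-2, search band in Hz (lo, hi).
#' @param bin_freqs bin-center frequencies, required when \code{spectrum} is a
#'   bare numeric vector.
#' @param interpolate if \code{TRUE}, refine the peak by parabolic
#'   interpolation over the neighboring bins (off by default: peaks are
#'   reported at bin resolution).
#' @param octave_ratio threshold for the octave-error guard (default 0.5);
#'   \code{NA} disables the guard.
#' @return An object of class \code{"char_freq"}: list with \code{f0} (Hz, or
#'   \code{NA} when the band contains no energy -- a "no peak" result, not an
#'   error), \code{band}, \code{peak_magnitude}, and \code{no_peak} flag.
#' @export
characteristic_frequency <- function(spectrum, band = c(120, 400),
                                     bin_freqs = NULL, interpolate = FALSE,
                                     octave_ratio = 0.5) {
  if (inherits(spectrum, "buzz_spectrum")) {
    bin_freqs <- spectrum$bin_freqs
    mag <- spectrum$magnitude
  } else {
    mag <- as.numeric(spectrum)
    if (is.null(bin_freqs))
      stop("bin_freqs must be supplied with a bare magnitude vector",
           call. = FALSE)
  }
  stopifnot(length(mag) == length(bin_freqs), length(band) == 2L,
            band[1L] <= band[2L])
  in_band <- which(bin_freqs >= band[1L] & bin_freqs <= band[2L])
  if (length(in_band) == 0L)
    stop("search band [", band[1L], ", ", band[2L],
         "] Hz intersects no frequency bin", call. = FALSE)
  if (all(mag[in_band] == 0)) {
    return(structure(list(f0 = NA_real_, band = band, peak_magnitude = 0,
                          no_peak = TRUE), class = "char_freq"))
  }
  peak_i <- in_band[which.max(mag[in_band])]  # which.max = first max: low tie
  ## octave-error guard: a harmonic series may have a weak fundamental
  if (!is.na(octave_ratio)) {
    half_f <- bin_freqs[peak_i] / 2
    if (half_f >= band[1L] && half_f >= bin_freqs[1L]) {
      half_i <- which.min(abs(bin_freqs - half_f))
      if (mag[half_i] > octave_ratio * mag[peak_i]) peak_i <- half_i
    }
  }
  f0 <- bin_freqs[peak_i]
  if (interpolate && peak_i > 1L && peak_i < length(mag)) {
    a <- mag[peak_i - 1L]; b <- mag[peak_i]; c <- mag[peak_i + 1L]
    denom <- a - 2 * b + c
    if (denom < 0) {
      delta <- 0.5 * (a - c) / denom
      f0 <- f0 + delta * (bin_freqs[2L] - bin_freqs[1L])
    }
  }
  structure(list(f0 = f0, band = band, peak_magnitude = mag[peak_i],
                 no_peak = FALSE), class = "char_freq")
}

#' @export
print.char_freq <- function(x, ...) {
  if (x$no_peak) {
    cat(sprintf("No spectral peak in band [%g, %g] Hz\n",
                x$band[1L], x$band[2L]))
  } else {
    cat(sprintf(
      "Characteristic frequency: %.2f Hz (peak magnitude %.4g, band [%g, %g] Hz)\n",
      x$f0, x$peak_magnitude, x$band[1L], x$band[2L]))
  }
  invisible(x)
}

#' Characteristic frequency of a recording segment
#'
#' Convenience wrapper: averaged Hamming power spectrum of the segment,
#' optional noise-profile subtraction, 3-bin sliding average, then band-peak
#' picking -- the full extraction workflow for one buzz.
#'
#' @inheritParams power_spectrum
#' @inheritParams characteristic_frequency
#' @param noise_profile optional per-bin noise magnitudes to subtract (aligned
#'   with the segment's spectrum bins).
#' @return A \code{"char_freq"} object.
#' @export
segment_charfreq <- function(rec, t0 = 0, t1 = NULL, band = c(120, 400),
                             fft_size = 8192L, noise_profile = NULL,
                             interpolate = FALSE) {
  ps <- power_spectrum(rec, t0, t1, fft_size = fft_size)
  mag <- ps$magnitude
  if (!is.null(noise_profile)) {
    if (length(noise_profile) != length(mag))
      stop("noise profile length does not match spectrum bins", call. = FALSE)
    mag <- pmax(mag - noise_profile, 0)
  }
  characteristic_frequency(smooth_spectrum(mag), band = band,
                           bin_freqs = ps$bin_freqs,
                           interpolate = interpolate)
}
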