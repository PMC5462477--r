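## Hamming is the default window everywhere: it is the window the
## characteristic-frequency workflow uses, and its -43 dB sidelobes set the
## dynamic-range floor used by the focal template.
window_vector <- function(window, n) {
  k <- seq(0L, n - 1L)
  switch(match.arg(window, c("hamming", "hann", "rect")),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / (n - 1)),
         hann    = 0.5 - 0.5 * cos(2 * pi * k / (n - 1)),
         rect    = rep(1, n))
}

#' Short-time Fourier transform spectrogram
#'
#' Frames the recording with a hop, applies the window, and returns DFT
#' magnitudes for the non-negative frequency bins. A spectrogram represents
#' the energy of the signal within time-frequency bins; all detection
#' operates on this object.
#'
#' @param rec a \code{\link{recording}}.
#' @param fft_size frame/FFT length in samples (>= 2).
#' @param hop hop between frame starts in samples (>= 1).
#' @param window window descriptor: \code{"hamming"} (default), \code{"hann"},
#'   or \code{"rect"}.
#' @return An object of class \code{"buzz_spectrogram"}: a list with
#'   \code{magnitudes} (frames x bins), \code{frame_times} (s, window
#'   centers), \code{bin_freqs} (Hz, bin centers, spacing
#'   \code{sample_rate / fft_size}), and the framing parameters.
#' @export
stft_spectrogram <- function(rec, fft_size = 1024L, hop = 256L,
                             window = "hamming") {
  stopifnot(inherits(rec, "buzz_recording"))
  fft_size <- as.integer(fft_size); hop <- as.integer(hop)
  if (fft_size < 2L || hop < 1L)
    stop("fft_size must be >= 2 and hop >= 1", call. = FALSE)
  n <- length(rec$samples)
  if (n < fft_size)
    stop("recording too short: ", n, " samples < one ", fft_size,
         "-sample analysis window", call. = FALSE)
  n_frames <- (n - fft_size) %/% hop + 1L
  w <- window_vector(window, fft_size)
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(fft_size), starts, `+`)   # fft_size x n_frames
  frames <- matrix(rec$samples[idx], nrow = fft_size) * w
  spec <- stats::mvfft(frames)
  n_bins <- fft_size %/% 2L + 1L
  mag <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))  # frames x bins
  structure(
    list(magnitudes = mag,
         frame_times = (starts + fft_size / 2) / rec$sample_rate,
         bin_freqs = (seq_len(n_bins) - 1L) * rec$sample_rate / fft_size,
         window = window, fft_size = fft_size, hop = hop,
         sample_rate = rec$sample_rate, source_id = rec$source_id),
    class = "buzz_spectrogram")
}

#' @export
print.buzz_spectrogram <- function(x, ...) {
  cat(sprintf(
    "Spectrogram of '%s': %d frames x %d bins (%s window, fft %d, hop %d)\n",
    x$source_id, nrow(x$magnitudes), ncol(x$magnitudes), x$window,
    x$fft_size, x$hop))
  cat(sprintf("  time %.3f..%.3f s, bins 0..%.1f Hz (%.2f Hz spacing)\n",
              x$frame_times[1L], x$frame_times[length(x$frame_times)],
              max(x$bin_freqs), x$bin_freqs[2L]))
  invisible(x)
}

#' @export
plot.buzz_spectrogram <- function(x, max_freq = 2000, ...) {
  keep <- x$bin_freqs <= max_freq
  graphics::image(x$frame_times, x$bin_freqs[keep],
                  log10(x$magnitudes[, keep, drop = FALSE] + 1e-12),
                  col = grDevices::gray.colors(64, rev = TRUE),
                  xlab = "Time (s)", ylab = "Frequency (Hz)", ...)
  invisible(x)
}

#' Export a spectrogram as a long-format CSV
#'
#' Columns \code{frame_time}, \code{bin_freq}, \code{magnitude}; intended for
#' debugging and external plotting.
#'
#' @param spec a \code{"buzz_spectrogram"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spectrogram_csv <- function(spec, path) {
  stopifnot(inherits(spec, "buzz_spectrogram"))
  df <- data.frame(
    frame_time = rep(spec$frame_times, times = ncol(spec$magnitudes)),
    bin_freq = rep(spec$bin_freqs, each = nrow(spec$magnitudes)),
    magnitude = as.vector(spec$magnitudes))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Estimate a noise profile from a quiet interval
#'
#' Per-bin mean magnitude over the frames whose centers fall in the half-open
#' interval \code{[t0, t1)} -- the analogue of selecting a one-second segment
#' of pure noise before noise removal.
#'
#' @param spec a \code{"buzz_spectrogram"}.
#' @param t0,t1 interval in seconds; must cover at least one frame.
#' @return Numeric vector of per-bin magnitudes aligned with
#'   \code{spec$bin_freqs}.
#' @export
estimate_noise_profile <- function(spec, t0, t1) {
  stopifnot(inherits(spec, "buzz_spectrogram"))
  sel <- spec$frame_times >= t0 & spec$frame_times < t1
  if (!any(sel))
    stop("noise interval [", t0, ", ", t1, ") covers no spectrogram frame",
         call. = FALSE)
  colMeans(spec$magnitudes[sel, , drop = FALSE])
}

#' Subtract a noise profile from a spectrogram
#'
#' Magnitude spectral subtraction floored at zero:
#' \code{max(magnitude - profile[bin], 0)} in every time-frequency bin.
#' Never increases any magnitude.
#'
#' @param spec a \code{"buzz_spectrogram"}.
#' @param profile per-bin noise magnitudes aligned with \code{spec$bin_freqs}.
#' @return The spectrogram with reduced magnitudes.
#' @export
subtract_noise <- function(spec, profile) {
  stopifnot(inherits(spec, "buzz_spectrogram"))
  if (length(profile) != ncol(spec$magnitudes))
    stop("noise profile length (", length(profile),
         ") does not match spectrogram bin count (", ncol(spec$magnitudes),
         ")", call. = FALSE)
  if (any(profile < 0)) stop("noise profile must be nonnegative", call. = FALSE)
  spec$magnitudes <- pmax(sweep(spec$magnitudes, 2L, profile), 0)
  spec
}

#' Three-bin sliding average of a spectrum
#'
#' Centered moving average across 3 frequency bins, the smoothing used before
#' picking the characteristic frequency. Edge bins average over the available
#' neighbors only (2 values), so constants pass through unchanged and edge
#' amplitudes are not biased downward.
#'
#' @param spectrum numeric vector of per-bin magnitudes (length >= 1).
#' @return Smoothed vector of the same length.
#' @export
smooth_spectrum <- function(spectrum) {
  n <- length(spectrum)
  if (n == 0L) stop("cannot smooth an empty spectrum", call. = FALSE)
  if (n == 1L) return(spectrum)
  if (n == 2L) return(rep(mean(spectrum), 2L))
  out <- spectrum
  out[2:(n - 1L)] <- (spectrum[1:(n - 2L)] + spectrum[2:(n - 1L)] +
                        spectrum[3:n]) / 3
  out[1L] <- mean(spectrum[1:2])
  out[n] <- mean(spectrum[(n - 1L):n])
  out
}

#' Average power spectrum of a recording segment
#'
#' Hamming-windowed magnitude spectrum averaged over all full frames inside
#' \code{[t0, t1)}, FFT size 8192 by default -- the settings used to measure
#' characteristic frequencies of individual buzzes.
#'
#' @param rec a \code{\link{recording}}.
#' @param t0,t1 segment in seconds (defaults: the whole recording).
#' @param fft_size FFT length in samples.
#' @param hop hop in samples (default \code{fft_size / 2}).
#' @param window window descriptor.
#' @return A list with \code{bin_freqs} (Hz) and \code{magnitude} (mean
#'   per-bin magnitude), of class \code{"buzz_spectrum"}.
#' @export
power_spectrum <- function(rec, t0 = 0, t1 = NULL, fft_size = 8192L,
                           hop = fft_size %/% 2L, window = "hamming") {
  stopifnot(inherits(rec, "buzz_recording"))
  if (is.null(t1)) t1 <- rec_duration(rec)
  i0 <- max(1L, floor(t0 * rec$sample_rate) + 1L)
  i1 <- min(length(rec$samples), ceiling(t1 * rec$sample_rate))
  if (i1 - i0 + 1L < fft_size)
    stop("segment too short for one ", fft_size, "-sample frame (",
         i1 - i0 + 1L, " samples); choose a longer segment or a smaller ",
         "fft_size (zero padding is off by default)", call. = FALSE)
  seg <- recording(rec$samples[i0:i1], rec$sample_rate, rec$source_id)
  spec <- stft_spectrogram(seg, fft_size = fft_size, hop = hop,
                           window = window)
  structure(list(bin_freqs = spec$bin_freqs,
                 magnitude = colMeans(spec$magnitudes),
                 fft_size = fft_size, window = window,
                 sample_rate = rec$sample_rate),
            class = "buzz_spectrum")
}

#' @export
print.buzz_spectrum <- function(x, ...) {
  cat(sprintf("Averaged power spectrum: %d bins, %.2f Hz spacing (%s, fft %d)\n",
              length(x$bin_freqs), x$bin_freqs[2L], x$window, x$fft_size))
  invisible(x)
}
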