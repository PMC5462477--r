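#' Detector configuration
#'
#' Bundles every tunable of the detection pipeline. Defaults target
#' 11.025 kHz field recordings: 1024-sample FFT with hop 256 gives
#' ~10.8 Hz x 23 ms time-frequency bins. Long recordings are processed in
#' overlapping chunks to bound the affinity matrix; detections merged across
#' chunk overlaps.
#'
#' @param fft_size,hop,window detection STFT parameters.
#' @param chunk_s,overlap_s chunk length and overlap in seconds.
#' @param template a \code{\link{focal_template_config}}.
#' @param sigma_t,sigma_f affinity kernel scales (frames, bins).
#' @param k number of spectral clusters per chunk (default 3, so simultaneous
#'   buzzes can land in separate clusters).
#' @param seed k-means seed (detection is deterministic given it).
#' @param kernel_len smashed-cluster convolution length in frames.
#' @param density_threshold,peak_threshold the two acceptance gates
#'   (both default 1.0, inclusive).
#' @param noise noise-profile strategy: \code{"median"} (per-chunk per-bin
#'   median magnitude, robust to buzzes occupying a minority of frames),
#'   \code{"profile"} (use \code{noise_profile}), or \code{"segment"} (mean
#'   magnitude over \code{noise_segment = c(t0, t1)} seconds of the
#'   recording).
#' @param noise_profile,noise_segment see \code{noise}.
#' @param band search band for per-event characteristic frequency (Hz).
#' @param merge_gap_s events closer than this are merged (default 0.1 s).
#' @param min_dur_s events shorter than this are dropped (default 0.05 s).
#' @return A list of class \code{"detector_config"}.
#' @export
detector_config <- function(fft_size = 1024L, hop = 256L, window = "hamming",
                            chunk_s = 3, overlap_s = 0.5,
                            template = focal_template_config(),
                            sigma_t = 5, sigma_f = 2, k = 3L, seed = 0L,
                            kernel_len = 20L, density_threshold = 1.0,
                            peak_threshold = 1.0,
                            noise = c("median", "profile", "segment"),
                            noise_profile = NULL, noise_segment = NULL,
                            band = c(120, 400), merge_gap_s = 0.1,
                            min_dur_s = 0.05) {
  noise <- match.arg(noise)
  stopifnot(chunk_s > overlap_s, overlap_s >= 0)
  structure(list(fft_size = as.integer(fft_size), hop = as.integer(hop),
                 window = window, chunk_s = chunk_s, overlap_s = overlap_s,
                 template = template, sigma_t = sigma_t, sigma_f = sigma_f,
                 k = as.integer(k), seed = as.integer(seed),
                 kernel_len = as.integer(kernel_len),
                 density_threshold = density_threshold,
                 peak_threshold = peak_threshold,
                 noise = noise, noise_profile = noise_profile,
                 noise_segment = noise_segment, band = band,
                 merge_gap_s = merge_gap_s, min_dur_s = min_dur_s),
            class = "detector_config")
}

#' Detect flight buzzes in a recording
#'
#' Runs the full CASA pipeline: chunked STFT, noise-profile subtraction,
#' harmonic focal template, Gaussian affinity over retained bins, spectral
#' clustering (k = 3), then the density (>= 1.0 points/frame) and
#' smashed-cluster (peak >= 1.0) gates. Accepted clusters become events;
#' events from overlapping chunks or split clusters are merged when they
#' overlap by more than half or sit closer than \code{merge_gap_s}. Each
#' event's characteristic frequency is the band peak of its averaged,
#' smoothed spectrum.
#'
#' Detection thresholds are noise-relative, so the event set is invariant
#' under uniform amplitude scaling of the recording.
#'
#' @param rec a \code{\link{recording}}.
#' @param cfg a \code{\link{detector_config}}.
#' @return An object of class \code{"buzz_events"}: a data frame with columns
#'   \code{source_id}, \code{start}, \code{end} (s), \code{f0} (Hz),
#'   \code{peak_score}, \code{density}, and \code{call} (always
#'   \code{"flight"}; a classification hook for pollination/sonication buzzes,
#'   which this detector does not separate). Attributes: \code{duration_s},
#'   \code{config}.
#' @export
detect_buzzes <- function(rec, cfg = detector_config()) {
  stopifnot(inherits(rec, "buzz_recording"), inherits(cfg, "detector_config"))
  dur <- rec_duration(rec)
  step_s <- cfg$chunk_s - cfg$overlap_s
  starts <- seq(0, max(0, dur - 1e-9), by = step_s)
  ## drop chunk starts that cannot hold a single analysis window
  starts <- starts[starts * rec$sample_rate + cfg$fft_size <=
                     length(rec$samples) + 1e-6]
  if (length(starts) == 0L)
    stop("recording too short: ", length(rec$samples),
         " samples < one analysis window", call. = FALSE)

  seg_profile <- NULL
  if (cfg$noise == "segment") {
    if (is.null(cfg$noise_segment))
      stop("noise = 'segment' requires noise_segment", call. = FALSE)
    full <- stft_spectrogram(rec, cfg$fft_size, cfg$hop, cfg$window)
    seg_profile <- estimate_noise_profile(full, cfg$noise_segment[1L],
                                          cfg$noise_segment[2L])
  }
  events <- list()
  for (cs in starts) {
    i0 <- floor(cs * rec$sample_rate) + 1L
    i1 <- min(length(rec$samples),
              floor((cs + cfg$chunk_s) * rec$sample_rate))
    if (i1 - i0 + 1L < cfg$fft_size) next
    chunk <- recording(rec$samples[i0:i1], rec$sample_rate, rec$source_id)
    spec <- stft_spectrogram(chunk, cfg$fft_size, cfg$hop, cfg$window)
    profile <- switch(cfg$noise,
      median = apply(spec$magnitudes, 2L, stats::median),
      profile = {
        if (is.null(cfg$noise_profile))
          stop("noise = 'profile' requires noise_profile", call. = FALSE)
        cfg$noise_profile
      },
      segment = seg_profile)
    sub <- subtract_noise(spec, profile)
    foc <- apply_focal_template(sub, profile, cfg$template)
    if (length(foc$frame) == 0L) next
    aff <- build_affinity(foc, cfg$sigma_t, cfg$sigma_f)
    labels <- spectral_cluster(aff, k = min(cfg$k, nrow(aff)),
                               seed = cfg$seed)
    half_win <- cfg$fft_size / (2 * rec$sample_rate)
    frame_hop_s <- cfg$hop / rec$sample_rate
    gap_frames <- max(1L, ceiling(cfg$merge_gap_s / frame_hop_s))
    for (lab in unique(labels)) {
      sel <- labels == lab
      cl <- tf_cluster(foc$frame[sel], foc$bin[sel])
      dens <- cluster_density(cl)
      if (dens$density < cfg$density_threshold) next
      sm <- smash_cluster(cl, cfg$kernel_len)
      if (sm$peak < cfg$peak_threshold) next
      ## event boundaries: runs of point-bearing frames (gaps above the merge
      ## gap split the cluster into separate events)
      occ <- sort(unique(cl$frame))
      run_id <- cumsum(c(1L, diff(occ) > gap_frames))
      for (r in unique(run_id)) {
        fr <- occ[run_id == r]
        mag <- colMeans(spec$magnitudes[fr, , drop = FALSE])
        cf <- characteristic_frequency(smooth_spectrum(pmax(mag - profile, 0)),
                                       band = cfg$band,
                                       bin_freqs = spec$bin_freqs)
        events[[length(events) + 1L]] <- data.frame(
          source_id = rec$source_id,
          start = cs + spec$frame_times[fr[1L]] - half_win,
          end = cs + spec$frame_times[fr[length(fr)]] + half_win,
          f0 = cf$f0, peak_score = sm$peak, density = dens$density,
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(source_id = character(0), start = numeric(0), end = numeric(0),
               f0 = numeric(0), peak_score = numeric(0), density = numeric(0),
               stringsAsFactors = FALSE)
  ev <- merge_events(ev, cfg$merge_gap_s)
  ev <- ev[ev$end - ev$start >= cfg$min_dur_s, , drop = FALSE]
  ev <- ev[order(ev$start), , drop = FALSE]
  rownames(ev) <- NULL
  ev$call <- rep("flight", nrow(ev))
  structure(ev, duration_s = dur, config = cfg,
            class = c("buzz_events", "data.frame"))
}

## Merge events that overlap by more than half of the shorter event or whose
## gap is below merge_gap_s (duplicates across chunk overlaps, split
## clusters). f0/peak/density taken from the longest constituent.
merge_events <- function(ev, merge_gap_s) {
  if (nrow(ev) <= 1L) return(ev)
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  out <- ev[1L, , drop = FALSE]
  best_len <- out$end[1L] - out$start[1L]
  for (i in 2:nrow(ev)) {
    j <- nrow(out)
    cur_len <- ev$end[i] - ev$start[i]
    overlap <- min(out$end[j], ev$end[i]) - max(out$start[j], ev$start[i])
    shorter <- min(out$end[j] - out$start[j], cur_len)
    gap <- ev$start[i] - out$end[j]
    if ((shorter > 0 && overlap > 0.5 * shorter) || gap < merge_gap_s) {
      out$end[j] <- max(out$end[j], ev$end[i])
      out$start[j] <- min(out$start[j], ev$start[i])
      out$peak_score[j] <- max(out$peak_score[j], ev$peak_score[i])
      if (cur_len > best_len) {  # adopt stats of the dominant constituent
        out$f0[j] <- ev$f0[i]
        out$density[j] <- ev$density[i]
        best_len <- cur_len
      }
    } else {
      out <- rbind(out, ev[i, , drop = FALSE])
      best_len <- cur_len
    }
  }
  out
}

#' @export
print.buzz_events <- function(x, ...) {
  cat(sprintf("%d buzz event(s) in %.1f s of audio\n",
              nrow(x), attr(x, "duration_s")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("  ... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' @export
summary.buzz_events <- function(object, ...) {
  dur_h <- attr(object, "duration_s") / 3600
  cat(sprintf("Buzz events: %d in %.3f h (%.1f buzzes/h)\n", nrow(object),
              dur_h, nrow(object) / dur_h))
  if (nrow(object))
    cat(sprintf("  f0: %.0f-%.0f Hz (median %.0f); duration %.2f-%.2f s\n",
                min(object$f0, na.rm = TRUE), max(object$f0, na.rm = TRUE),
                median(object$f0, na.rm = TRUE),
                min(object$end - object$start),
                max(object$end - object$start)))
  invisible(object)
}

#' @export
plot.buzz_events <- function(x, ...) {
  if (!nrow(x)) {
    plot(0, 0, type = "n", xlab = "Time (s)", ylab = "f0 (Hz)",
         main = "No buzz events")
    return(invisible(x))
  }
  plot((x$start + x$end) / 2, x$f0, xlab = "Time (s)",
       ylab = "Characteristic frequency (Hz)", pch = 19, ...)
  invisible(x)
}

#' Buzz density (buzzes per hour)
#'
#' The acoustic proxy for pollinator activity: detected buzz count divided by
#' recording duration. Concatenating recordings sums counts and durations, so
#' pooled density is the duration-weighted mean.
#'
#' @param events a \code{"buzz_events"} object, a data frame of events, or an
#'   event count.
#' @param hours recording duration in hours (> 0); defaults to the duration
#'   recorded on a \code{"buzz_events"} object.
#' @return Buzzes per hour.
#' @export
buzz_density <- function(events, hours = NULL) {
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  if (is.null(hours) && inherits(events, "buzz_events"))
    hours <- attr(events, "duration_s") / 3600
  if (is.null(hours) || !is.numeric(hours) || hours <= 0)
    stop("'hours' must be a positive duration", call. = FALSE)
  n / hours
}

#' Write detected events to CSV
#'
#' @param events a \code{"buzz_events"} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
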