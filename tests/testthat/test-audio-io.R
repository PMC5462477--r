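test_that("WAV round trip preserves samples, rate and mono reduction", {
  set.seed(11)
  x <- runif(4410, -0.5, 0.5)
  rec <- recording(x, 11025, "toy")
  p16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, p16, bits = 16L)
  back <- read_wav(p16)
  expect_equal(back$sample_rate, 11025)
  expect_equal(length(back$samples), 4410)
  expect_lt(max(abs(back$samples - x)), 1 / 32767)

  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, p32, bits = 32L)
  expect_equal(read_wav(p32)$samples, x, tolerance = 1e-7)
})

test_that("zero and full-scale PCM decode to 0 and ~1", {
  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(recording(rep(0, 11025), 11025), p)
  z <- read_wav(p)
  expect_equal(length(z), 11025L)
  expect_true(all(z$samples == 0))

  write_wav(recording(rep(1, 100), 8000), p)
  expect_equal(read_wav(p)$samples, rep(1, 100), tolerance = 1e-3)
})

test_that("stereo files mix to the hand-computed channel mean", {
  ## hand-build a 4-sample stereo 16-bit PCM file: L = (0.5, -0.5, 0.25, 0),
  ## R = (0.1, 0.3, -0.25, 0.2); mix = (0.3, -0.1, 0, 0.1)
  p <- withr::local_tempfile(fileext = ".wav")
  con <- file(p, "wb")
  samp <- as.integer(round(c(0.5, 0.1, -0.5, 0.3, 0.25, -0.25, 0, 0.2) * 32767))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 16L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # stereo
  writeBin(8000L, con, size = 4, endian = "little")
  writeBin(32000L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(samp, con, size = 2, endian = "little")
  close(con)
  mix <- read_wav(p, channel_policy = "mix")
  expect_equal(mix$samples, c(0.3, -0.1, 0, 0.1), tolerance = 1e-3)
  first <- read_wav(p, channel_policy = "first")
  expect_equal(first$samples, c(0.5, -0.5, 0.25, 0), tolerance = 1e-3)
})

test_that("unreadable input fails with an informative error", {
  expect_error(read_wav("/nonexistent/file.wav"), "nonexistent")
  p <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio at all, just text padding out some bytes", p)
  expect_error(read_wav(p), "RIFF")
})

test_that("STFT matches a direct windowed DFT on small signals", {
  set.seed(21)
  x <- rnorm(96)
  rec <- recording(x, 48, "dft-oracle")
  spec <- stft_spectrogram(rec, fft_size = 32L, hop = 32L)
  expect_equal(nrow(spec$magnitudes), 3L)  # floor((96-32)/32)+1
  for (f in 1:3) {
    frame <- x[((f - 1) * 32 + 1):((f - 1) * 32 + 32)]
    expect_equal(spec$magnitudes[f, ], direct_dft_mag(frame),
                 tolerance = 1e-9)
  }
})

test_that("STFT localizes a pure tone and returns zeros for silence", {
  sr <- 44100
  tone <- recording(sin(2 * pi * 175 * seq_len(sr) / sr), sr)
  spec <- stft_spectrogram(tone, fft_size = 8192L, hop = 4096L)
  peaks <- spec$bin_freqs[apply(spec$magnitudes, 1L, which.max)]
  expect_true(all(abs(peaks - 175) <= sr / 8192))

  silent <- recording(rep(0, 4096), 11025)
  expect_true(all(stft_spectrogram(silent, 1024L, 256L)$magnitudes == 0))
  expect_error(stft_spectrogram(recording(rep(0, 100), 11025), 1024L),
               "too short")
})

test_that("spectrogram axes obey the stated coordinate invariants", {
  rec <- noise_recording(1)
  spec <- stft_spectrogram(rec, 1024L, 256L)
  expect_true(all(diff(spec$frame_times) > 0))
  expect_true(all(diff(spec$bin_freqs) > 0))
  expect_equal(spec$bin_freqs[2] - spec$bin_freqs[1], 11025 / 1024)
  expect_true(all(spec$magnitudes >= 0))
})

test_that("noise profile is the per-bin mean over the selected frames", {
  rec <- noise_recording(1)
  spec <- stft_spectrogram(rec, 1024L, 256L)
  ## hand-summed small case on a 3x4 sub-matrix pasted into the object
  spec$magnitudes <- matrix(c(1, 2, 3, 4,  5, 6, 7, 8,  9, 10, 11, 12),
                            nrow = 3, byrow = TRUE)
  spec$frame_times <- c(0.1, 0.2, 0.3)
  spec$bin_freqs <- c(0, 10, 20, 30)
  expect_equal(estimate_noise_profile(spec, 0, 1), c(5, 6, 7, 8))
  ## interval spanning exactly one frame returns that frame's row
  expect_equal(estimate_noise_profile(spec, 0.25, 0.35), c(9, 10, 11, 12))
  expect_error(estimate_noise_profile(spec, 5, 6), "no spectrogram frame")

  const <- spec; const$magnitudes <- matrix(2.5, 3, 4)
  expect_equal(estimate_noise_profile(const, 0, 1), rep(2.5, 4))
})

test_that("noise subtraction is the element-wise floored difference", {
  rec <- noise_recording(0.5)
  spec <- stft_spectrogram(rec, 1024L, 256L)
  spec$magnitudes <- matrix(c(5, 1, 0,  2, 3, 4,  7, 0, 1), 3, byrow = TRUE)
  spec$bin_freqs <- c(0, 10, 20); spec$frame_times <- 1:3
  out <- subtract_noise(spec, c(3, 2, 2))
  expect_equal(out$magnitudes,
               matrix(c(2, 0, 0,  0, 1, 2,  4, 0, 0), 3, byrow = TRUE))
  ## identity and annihilation limits
  expect_equal(subtract_noise(spec, c(0, 0, 0))$magnitudes, spec$magnitudes)
  const <- spec; const$magnitudes <- matrix(2, 3, 3)
  expect_true(all(subtract_noise(const, rep(2, 3))$magnitudes == 0))
  expect_error(subtract_noise(spec, 1:5), "does not match")
})

test_that("noise subtraction never increases any magnitude", {
  set.seed(31)
  for (i in 1:5) {
    spec <- stft_spectrogram(noise_recording(0.3), 512L, 128L)
    prof <- runif(ncol(spec$magnitudes), 0, 0.5)
    expect_true(all(subtract_noise(spec, prof)$magnitudes <=
                      spec$magnitudes))
  }
})

test_that("3-bin sliding average matches hand computation and edge rules", {
  expect_equal(smooth_spectrum(c(0, 3, 0, 3, 0)), c(1.5, 1, 2, 1, 1.5))
  expect_equal(smooth_spectrum(rep(4, 7)), rep(4, 7))   # constants unchanged
  expect_equal(smooth_spectrum(5), 5)                   # single bin
  expect_error(smooth_spectrum(numeric(0)), "empty")
  ## interior mean preserved for periodic input
  x <- rep(c(1, 2, 3), 6)
  s <- smooth_spectrum(x)
  expect_equal(mean(s[2:17]), mean(x[2:17]))
  expect_equal(length(s), length(x))
})
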