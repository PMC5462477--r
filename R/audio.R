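#' Construct a mono recording
#'
#' The raw acoustic unit used throughout the package: a mono amplitude
#' sequence (nominally in -1..1) with its sample rate.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param source_id free-text identifier carried into detection output.
#' @return An object of class \code{"buzz_recording"}.
#' @export
recording <- function(samples, sample_rate, source_id = "recording") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         source_id = as.character(source_id)[1L]),
    class = "buzz_recording")
}

#' @export
print.buzz_recording <- function(x, ...) {
  cat(sprintf("Mono recording '%s': %d samples @ %g Hz (%.3f s)\n",
              x$source_id, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.buzz_recording <- function(x) length(x$samples)

## duration in seconds
rec_duration <- function(rec) length(rec$samples) / rec$sample_rate

#' Read a RIFF/WAVE file as a mono recording
#'
#' Supports uncompressed PCM (16/24/32-bit integer) and IEEE float (32-bit),
#' mono or stereo. Stereo is reduced to mono by channel averaging
#' (\code{channel_policy = "mix"}) or by keeping the first channel.
#' Integer samples are rescaled to -1..1.
#'
#' @param path path to a .wav file.
#' @param channel_policy \code{"mix"} (default) or \code{"first"}.
#' @return A \code{\link{recording}}.
#' @export
read_wav <- function(path, channel_policy = c("mix", "first")) {
  channel_policy <- match.arg(channel_policy)
  if (!file.exists(path) || file.info(path)$size == 0)
    stop("cannot read audio file (missing or empty): ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format    = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels  = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate      = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits      = sum(as.integer(body[15:16]) * c(1L, 256L)))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L)
    stop("malformed or empty WAVE file: ", path, call. = FALSE)
  if (!fmt$format %in% c(1L, 3L))
    stop("codec unsupported (WAVE format tag ", fmt$format,
         "); only PCM and IEEE float are readable", call. = FALSE)

  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n, size = 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    i1 <- seq(1L, by = 3L, length.out = n)
    v <- b[i1] + 256 * b[i1 + 1L] + 65536 * b[i1 + 2L]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else {
    stop("codec unsupported: ", fmt$bits, "-bit format tag ", fmt$format,
         call. = FALSE)
  }

  if (fmt$channels > 1L) {
    m <- matrix(x[seq_len((n %/% fmt$channels) * fmt$channels)],
                nrow = fmt$channels)
    x <- if (channel_policy == "mix") colMeans(m) else m[1L, ]
  }
  recording(x, fmt$rate, source_id = basename(path))
}

#' Write a recording to a WAV file
#'
#' @param rec a \code{\link{recording}}.
#' @param path output path.
#' @param bits 16 (integer PCM, default) or 32 (IEEE float).
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "buzz_recording"), bits %in% c(16L, 32L))
  x <- rec$samples
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- length(x) * (bits %/% 8L)
  wtag <- if (bits == 16L) 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nbytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(wtag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * bits %/% 8L), con, size = 4,
           endian = "little")
  writeBin(as.integer(bits %/% 8L), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}
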