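#' ERB-number scale conversions
#'
#' Glasberg-Moore ERB-number scale:
#' \eqn{ERB_n(f) = 21.4 \log_{10}(4.37 f / 1000 + 1)} and its inverse, plus
#' the equivalent rectangular bandwidth
#' \eqn{ERB(f) = 24.7 (4.37 f / 1000 + 1)} in Hz.
#'
#' @param f Frequency in Hz.
#' @param e ERB number.
#' @return Converted values.
#' @export
hz_to_erb <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname hz_to_erb
#' @export
erb_to_hz <- function(e) (10 ^ (e / 21.4) - 1) * 1000 / 4.37

#' @rdname hz_to_erb
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' ERB-spaced filterbank center frequencies
#'
#' n frequencies equally spaced on the ERB-number scale between
#' \code{fmin} and \code{fmax}, endpoints included; the spacing used for
#' the cochlear front end (default 50-8000 Hz).
#'
#' @param n Number of channels (>= 2).
#' @param fmin,fmax Frequency range in Hz, 0 < fmin < fmax.
#' @return Strictly increasing numeric vector of length n.
#' @export
#' @examples
#' erb_center_freqs(3)  # endpoints 50 and 8000, ERB-scale midpoint between
erb_center_freqs <- function(n, fmin = 50, fmax = 8000) {
  if (!(fmin > 0 && fmax > fmin)) stop("need 0 < fmin < fmax", call. = FALSE)
  stopifnot(n >= 2)
  erb_to_hz(seq(hz_to_erb(fmin), hz_to_erb(fmax), length.out = n))
}

# truncated 4th-order gammatone impulse response at center frequency f,
# normalized to unit gain at f
gammatone_kernel <- function(f, fs, order = 4) {
  b <- 1.019 * erb_bandwidth(f)
  decay <- 2 * pi * b
  len_s <- min(0.12, max(0.008, 12 / decay))
  t <- seq(0, len_s, by = 1 / fs)
  g <- t ^ (order - 1) * exp(-decay * t) * cos(2 * pi * f * t)
  h <- sum(g * exp(-1i * 2 * pi * f * t))
  g / Mod(h)
}

#' Cochleagram of an audio waveform
#'
#' Linear cochlear front end: a bank of 4th-order gammatone filters with
#' Glasberg-Moore bandwidths at ERB-spaced center frequencies, followed by
#' half-wave rectification and low-pass filtering (a stand-in for the
#' phase-locking limit of auditory-nerve firing), then averaging into
#' frames.  The filterbank stage is linear; all nonlinearity enters at the
#' rectifier.
#'
#' @param audio Numeric waveform (mono; a 2-column matrix is averaged to
#'   mono).
#' @param fs Sampling rate (Hz); must be at least \code{2 * fmax}.
#' @param n_channels Number of channels (default 32).
#' @param frame_ms Frame length for averaging (ms, default 1).
#' @param fmin,fmax Filterbank range (Hz, default 50-8000).
#' @param lp_cutoff Low-pass cutoff after rectification (Hz, default 1000).
#' @param rectify Apply rectification + low-pass (default \code{TRUE});
#'   disable to inspect the linear filterbank stage.
#' @return An object of class \code{"cochleagram"}: list with
#'   \code{activity} (non-negative n_channels x n_frames matrix),
#'   \code{center_freqs}, \code{frame_ms}.
#' @export
cochleagram <- function(audio, fs, n_channels = 32, frame_ms = 1,
                        fmin = 50, fmax = 8000, lp_cutoff = 1000,
                        rectify = TRUE) {
  if (is.matrix(audio)) audio <- rowMeans(audio)
  audio <- as.numeric(audio)
  if (fs < 2 * fmax)
    stop("sampling rate ", fs, " Hz is below 2 * fmax = ", 2 * fmax,
         call. = FALSE)
  cfs <- erb_center_freqs(n_channels, fmin, fmax)
  n <- length(audio)
  spf <- max(1L, as.integer(round(frame_ms / 1000 * fs)))
  n_frames <- n %/% spf
  act <- matrix(0, n_channels, n_frames)
  lp <- signal::butter(2, min(0.99, lp_cutoff / (fs / 2)), type = "low")
  for (k in seq_len(n_channels)) {
    ker <- gammatone_kernel(cfs[k], fs)
    y <- stats::convolve(audio, rev(ker), type = "open")[seq_len(n)]
    if (rectify) {
      y <- pmax(y, 0)
      y <- as.numeric(signal::filter(lp, y))
      y <- pmax(y, 0)
    }
    act[k, ] <- colMeans(matrix(y[seq_len(n_frames * spf)], nrow = spf))
  }
  if (!rectify) act <- act else act[act < 0] <- 0
  structure(list(activity = act, center_freqs = cfs, frame_ms = frame_ms),
            class = "cochleagram")
}

#' @export
print.cochleagram <- function(x, ...) {
  cat(sprintf("Cochleagram: %d channels (%.0f-%.0f Hz) x %d frames of %g ms\n",
              nrow(x$activity), min(x$center_freqs), max(x$center_freqs),
              ncol(x$activity), x$frame_ms))
  invisible(x)
}

#' Threshold a cochleagram into a binary stimulus pattern
#'
#' Cells with activity at or above \code{threshold} times the global maximum
#' become active; bridges real audio into the binary-pattern pipeline.
#'
#' @param coch A \code{\link{cochleagram}}.
#' @param threshold Fraction of the maximum activity, in (0, 1).
#' @return A \code{\link{stimulus_pattern}} with \code{bin_ms = frame_ms}.
#' @export
activity_to_pattern <- function(coch, threshold = 0.15) {
  stopifnot(inherits(coch, "cochleagram"),
            threshold > 0, threshold < 1)
  grid <- 1 * (coch$activity >= threshold * max(coch$activity))
  stimulus_pattern(grid, bin_ms = coch$frame_ms, label = "audio")
}

#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader for uncompressed PCM (8/16/24/32-bit integer)
#' and 32-bit IEEE float files; stereo is averaged to mono.  Samples are
#' scaled to [-1, 1].
#'
#' @param path Path to a .wav file.
#' @return List with \code{samples} (numeric vector) and \code{fs} (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data))
    stop("missing fmt or data chunk", call. = FALSE)
  bytes <- fmt$bits %/% 8
  n <- length(data) %/% bytes
  if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(data, "numeric", n, 4, endian = "little")
  } else if (fmt$audio_format == 1) {
    x <- switch(as.character(fmt$bits),
      "8" = (as.numeric(readBin(data, "integer", n, 1, signed = FALSE)) -
               128) / 128,
      "16" = readBin(data, "integer", n, 2, signed = TRUE,
                     endian = "little") / 32768,
      "24" = {
        m <- matrix(as.integer(data[seq_len(n * 3)]), nrow = 3)
        v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
        ifelse(v >= 2^23, v - 2^24, v) / 2^23
      },
      "32" = readBin(data, "integer", n, 4, signed = TRUE,
                     endian = "little") / 2^31,
      stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE))
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")",
         call. = FALSE)
  }
  if (fmt$n_channels > 1) {
    nf <- length(x) %/% fmt$n_channels
    x <- colMeans(matrix(x[seq_len(nf * fmt$n_channels)],
                         nrow = fmt$n_channels))
  }
  list(samples = x, fs = fmt$fs)
}

#' Cochleagram straight from a WAV file
#'
#' @param path Path to a PCM WAV file.
#' @param ... Passed to \code{\link{cochleagram}}.
#' @return A \code{\link{cochleagram}}.
#' @export
wav_to_cochleagram <- function(path, ...) {
  w <- read_wav(path)
  cochleagram(w$samples, w$fs, ...)
}
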