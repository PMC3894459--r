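test_that("ERB spacing includes endpoints and inverts at the scale midpoint", {
  expect_equal(erb_center_freqs(2, 50, 8000), c(50, 8000))
  f3 <- erb_center_freqs(3, 50, 8000)
  expect_equal(f3[2], erb_to_hz((hz_to_erb(50) + hz_to_erb(8000)) / 2))
  for (n in c(3, 8, 32))
    expect_true(all(diff(erb_center_freqs(n, 50, 8000)) > 0))
  expect_error(erb_center_freqs(3, 100, 50), "fmin")
})

test_that("silence yields an all-zero cochleagram and low fs errors", {
  co <- cochleagram(numeric(4000), fs = 16000, n_channels = 8, fmax = 4000)
  expect_true(all(co$activity == 0))
  expect_error(cochleagram(numeric(100), fs = 8000), "sampling rate")
})

test_that("pure tones concentrate energy in their own channel", {
  fs <- 16000
  n_ch <- 16
  cfs <- erb_center_freqs(n_ch, 50, 4000)
  t <- seq(0, 0.25, by = 1 / fs)
  for (k in c(4, 8, 13)) {
    tone <- sin(2 * pi * cfs[k] * t)
    co <- cochleagram(tone, fs, n_channels = n_ch, fmax = 4000)
    act <- rowMeans(co$activity)
    expect_equal(which.max(act), k)
    # at least 3 dB localization against channels four away
    for (j in c(k - 4, k + 4)) {
      if (j >= 1 && j <= n_ch)
        expect_gt(10 * log10(act[k] / act[j]), 3)
    }
  }
})

test_that("an upward chirp produces a non-decreasing activity ridge", {
  fs <- 16000
  t <- seq(0, 0.5, by = 1 / fs)
  f0 <- 300; f1 <- 3000
  chirp <- sin(2 * pi * (f0 * t + (f1 - f0) * t ^ 2 / (2 * 0.5)))
  co <- cochleagram(chirp, fs, n_channels = 16, frame_ms = 20, fmax = 4000)
  ridge <- apply(co$activity, 2, which.max)
  mid <- ridge[3:(length(ridge) - 2)]     # ignore onset/offset edges
  expect_true(all(diff(mid) >= 0))
  expect_gt(utils::tail(mid, 1), mid[1])
})

test_that("the filterbank stage is linear before rectification", {
  fs <- 16000
  set.seed(2)
  a <- rnorm(2000); b <- rnorm(2000)
  ca <- cochleagram(a, fs, n_channels = 6, fmax = 4000, rectify = FALSE)
  cb <- cochleagram(b, fs, n_channels = 6, fmax = 4000, rectify = FALSE)
  cab <- cochleagram(a + b, fs, n_channels = 6, fmax = 4000, rectify = FALSE)
  expect_equal(cab$activity, ca$activity + cb$activity, tolerance = 1e-10)
})

test_that("binary pattern extraction is monotone in the threshold", {
  fs <- 16000
  t <- seq(0, 0.1, by = 1 / fs)
  co <- cochleagram(sin(2 * pi * 1000 * t), fs, n_channels = 8,
                    frame_ms = 10, fmax = 4000)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                   function(th) sum(activity_to_pattern(co, th)$grid),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # all-equal activity with mid threshold: everything active
  flat <- structure(list(activity = matrix(1, 4, 5), center_freqs = 1:4,
                         frame_ms = 1), class = "cochleagram")
  expect_true(all(activity_to_pattern(flat, 0.5)$grid == 1))
})

test_that("PCM WAV files round-trip through the reader", {
  fs <- 8000L
  x <- sin(2 * pi * 440 * seq(0, 0.05, by = 1 / fs)) * 0.5
  path <- withr::local_tempfile(fileext = ".wav")
  # hand-assemble a minimal 16-bit PCM mono WAV
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")
  writeBin(c(fs, 2L * fs), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  close(con)
  w <- read_wav(path)
  expect_equal(w$fs, fs)
  expect_equal(w$samples, pcm / 32768)
  expect_lt(max(abs(w$samples - x)), 1e-4)
})
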