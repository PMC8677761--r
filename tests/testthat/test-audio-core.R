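test_that("WAV round trips preserve samples within bit-depth quantization", {
  f <- withr::local_tempfile(fileext = ".wav")

  zeros <- audio_clip(rep(0, 44100), 44100)
  write_wav(zeros, f, "16")
  back <- read_wav(f)
  expect_equal(length(back$samples), 44100)
  expect_equal(back$sample_rate, 44100)
  expect_true(all(back$samples == 0))

  sine <- make_tone(550, dur = 0.5, amps = 0.9)
  write_wav(sine, f, "float32")
  expect_lt(max(abs(read_wav(f)$samples - sine$samples)), 1e-6)

  write_wav(sine, f, "16")
  expect_lt(max(abs(read_wav(f)$samples - sine$samples)), 1 / 32768)

  write_wav(sine, f, "24")
  expect_lt(max(abs(read_wav(f)$samples - sine$samples)), 1 / 8388608)
})

test_that("stereo WAV files downmix to the common channel", {
  # hand-built PCM16 stereo file with identical channels
  f <- withr::local_tempfile(fileext = ".wav")
  sr <- 8000L
  x <- round(0.4 * sin(2 * pi * 440 * (0:7999) / sr) * 32767)
  inter <- as.integer(rbind(x, x))
  con <- file(f, "wb")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + length(inter) * 2L)
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(1L); w16(2L); w32(sr); w32(sr * 4L); w16(4L); w16(16L)
  writeChar("data", con, eos = NULL); w32(length(inter) * 2L)
  writeBin(inter, con, size = 2L, endian = "little")
  close(con)
  clip <- read_wav(f)
  expect_equal(clip$sample_rate, sr)
  expect_equal(clip$samples, x / 32768, tolerance = 1e-12)
})

test_that("unreadable files and invalid samples are rejected", {
  expect_error(read_wav(tempfile()), "unreadable")
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav at all, just text padding to pass size", f)
  expect_error(read_wav(f), "RIFF")
  clip <- audio_clip(rep(0, 16000), 16000)
  clip$samples[5] <- NaN
  expect_error(write_wav(clip, f), "non-finite")
  expect_error(audio_clip(c(0, NA, 0), 44100), "finite")
  expect_error(audio_clip(rep(2, 100), 44100), "full scale")
  expect_error(audio_clip(rep(0, 100), 4000), "8000")
})

test_that("spectrogram geometry and energy are consistent", {
  clip <- make_tone(550, dur = 1)
  sp <- compute_spectrogram(clip)
  geom <- attr(sp, "geom")
  # exact frame count
  expect_equal(length(sp$times),
               floor((length(clip$samples) - geom$W) / geom$hop) + 1)
  # single tone: argmax bin within one native bin of 550 Hz
  j <- which.max(sp$mag[, ncol(sp$mag) %/% 2])
  expect_lt(abs(sp$freqs[j] - 550), clip$sample_rate / geom$W + 1e-9)
  # Parseval: spectral power within 1% of windowed time-domain power
  fr <- 10L
  i0 <- (fr - 1L) * geom$hop
  xw <- clip$samples[i0 + seq_len(geom$W)] * geom$window
  raw <- sp$mag[, fr] / swarmtone:::mag_scale(geom)
  nb <- length(raw)
  p_spec <- (raw[1]^2 + raw[nb]^2 + 2 * sum(raw[2:(nb - 1)]^2)) / geom$nfft
  expect_equal(p_spec, sum(xw^2), tolerance = 0.01)
})

test_that("chirp ridge rises monotonically and silence sits at the floor", {
  sr <- 8000
  t <- seq(0, 10 - 1 / sr, by = 1 / sr)
  chirp <- audio_clip(0.5 * sin(2 * pi * (500 * t + 5 * t^2)), sr)
  sp <- compute_spectrogram(chirp, max_freq = 1000)
  ridge <- sp$freqs[apply(sp$mag, 2, which.max)]
  expect_true(all(diff(ridge) > -3))          # monotone up to bin noise
  expect_gt(ridge[length(ridge)] - ridge[1], 80)

  sil <- compute_spectrogram(audio_clip(rep(0, 8000), 8000))
  expect_true(all(sil$db == -120))
})

test_that("clips shorter than one window are rejected", {
  expect_error(compute_spectrogram(audio_clip(rep(0, 1000), 44100)),
               "shorter than one")
})

test_that("peak_in_band refines single tones and gates on prominence", {
  clip <- make_tone(552, dur = 0.5)
  sp <- compute_spectrogram(clip)
  pk <- peak_in_band(sp, 0.25, c(400, 700))
  expect_lt(abs(pk$f0 - 552), 2)

  # dominant peak wins between two tones
  two <- make_tone(c(550, 600), dur = 0.5, amps = c(0.1, 0.0178))
  pk2 <- peak_in_band(compute_spectrogram(two), 0.25, c(400, 700))
  expect_lt(abs(pk2$f0 - 550), 2)

  # white noise only: no tonal peak survives the 6 dB gate
  withr::with_seed(11, {
    noise <- audio_clip(rnorm(22050, 0, 0.05), 44100)
  })
  expect_null(peak_in_band(compute_spectrogram(noise), 0.25, c(400, 700)))

  expect_error(peak_in_band(sp, 0.25, c(400, 400.5)), "band")
  expect_error(peak_in_band(sp, 0.25, c(400, 50000)), "range")
})

test_that("peak frequency error stays below half the refined bin width", {
  withr::with_seed(303, {
    freqs <- runif(50, 400, 1000)
  })
  sr <- 22050
  errs <- vapply(freqs, function(f) {
    sp <- compute_spectrogram(make_tone(f, dur = 0.3, sr = sr))
    pk <- peak_in_band(sp, 0.15, c(350, 1050))
    abs(pk$f0 - f)
  }, numeric(1))
  binw <- sr / attr(compute_spectrogram(make_tone(500, 0.3, sr)),
                    "geom")$nfft
  expect_lt(max(errs), binw / 2)
})
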