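# Short-time Fourier machinery shared by the spectrogram, noise-reduction
# and tracking layers. Magnitudes are sine-calibrated: a full-scale sine at
# a bin centre reads mag = 1 (0 dBFS), so amplitude criteria expressed in
# dB differences are independent of the window.

DB_FLOOR <- -120

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

next_pow2 <- function(n) 2^ceiling(log2(n))

stft_geometry <- function(sample_rate, window_s, overlap, zero_pad = 1) {
  W <- round(window_s * sample_rate)
  W <- W + W %% 2L                      # even length keeps hop arithmetic tidy
  if (W < 64L) stop("window too short: need window_s * sample_rate >= 64")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  hop <- max(1L, round(W * (1 - overlap)))
  nfft <- next_pow2(W * zero_pad)
  list(W = as.integer(W), hop = as.integer(hop), nfft = as.integer(nfft),
       window = hann_window(W), sample_rate = sample_rate,
       window_s = window_s, overlap = overlap)
}

# Frame a signal: matrix W x n_frames of windowed samples.
# n_frames = floor((N - W)/hop) + 1 exactly.
frame_signal <- function(x, geom, starts = NULL) {
  N <- length(x)
  if (N < geom$W) stop("clip shorter than one analysis window")
  if (is.null(starts)) starts <- seq(1L, N - geom$W + 1L, by = geom$hop)
  idx <- outer(0:(geom$W - 1L), starts, "+")
  matrix(x[idx], nrow = geom$W) * geom$window
}

# One-sided complex STFT of pre-framed data (zero-padded FFT).
stft_fft <- function(frames, geom, onesided = TRUE) {
  nfft <- geom$nfft
  if (nrow(frames) < nfft)
    frames <- rbind(frames, matrix(0, nfft - nrow(frames), ncol(frames)))
  X <- stats::mvfft(frames)
  if (onesided) X[seq_len(nfft / 2 + 1L), , drop = FALSE] else X
}

mag_scale <- function(geom) 2 / sum(geom$window)

#' Compute a magnitude spectrogram
#'
#' Short-time Fourier spectrogram with a Hann window and zero-padded FFT.
#' Frame spacing is `window_s * (1 - overlap)`; bin spacing is
#' `sample_rate / nfft` where the FFT length is the next power of two of
#' `zero_pad` times the window length (zero-padding refines the bin grid).
#' Magnitudes are calibrated so a full-scale sine reads 1 (0 dBFS);
#' `db = 20 log10(mag)` floored at -120 dBFS.
#'
#' @param clip An [audio_clip()].
#' @param window_s Analysis window length in seconds. The default,
#'   4096 samples at 44.1 kHz, gives ~2.7 Hz bin spacing after 4x padding.
#' @param overlap Fractional window overlap in \[0, 1); default 0.75.
#' @param zero_pad FFT zero-padding factor (default 4).
#' @param max_freq Optional upper frequency bound; bins above it are
#'   dropped to save memory.
#' @return A `spectrogram`: list with `times` (frame centres, s), `freqs`
#'   (bin centres, Hz), `mag` (bins x frames magnitude matrix) and `db`.
#' @export
compute_spectrogram <- function(clip, window_s = 4096 / 44100,
                                overlap = 0.75, zero_pad = 4,
                                max_freq = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  geom <- stft_geometry(clip$sample_rate, window_s, overlap, zero_pad)
  frames <- frame_signal(clip$samples, geom)
  X <- stft_fft(frames, geom)
  mag <- Mod(X) * mag_scale(geom)
  freqs <- (seq_len(nrow(mag)) - 1L) * clip$sample_rate / geom$nfft
  if (!is.null(max_freq)) {
    keep <- freqs <= max_freq
    mag <- mag[keep, , drop = FALSE]
    freqs <- freqs[keep]
  }
  starts <- seq(1L, length(clip$samples) - geom$W + 1L, by = geom$hop)
  times <- (starts - 1L + geom$W / 2) / clip$sample_rate
  db <- 20 * log10(pmax(mag, 10^(DB_FLOOR / 20)))
  structure(list(times = times, freqs = freqs, mag = mag, db = db),
            geom = geom, class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d frames x %d bins, t %.2f-%.2f s, f %.1f-%.1f Hz\n",
    length(x$times), length(x$freqs), min(x$times), max(x$times),
    min(x$freqs), max(x$freqs)))
  invisible(x)
}

# Parabolic (3-point) interpolation of a peak in the dB domain.
# Returns list(delta = sub-bin offset in bins, value = interpolated dB).
parabolic_refine <- function(a, b, c) {
  denom <- a + c - 2 * b
  delta <- ifelse(abs(denom) < 1e-12, 0, (a - c) / (2 * denom))
  delta <- pmax(pmin(delta, 0.5), -0.5)
  alpha <- denom / 2
  beta <- (c - a) / 2
  list(delta = delta, value = b + beta * delta + alpha * delta^2)
}

# Vectorised band peak extraction over all frames of a band sub-matrix.
# db_band: bins x frames matrix (dB); freqs_band: bin centres. A tone is
# reported only when the band maximum is an interior local maximum (a
# band-edge maximum is the skirt of a tone centred outside the band) that
# stands prominence_db above the band's median level.
band_peaks_core <- function(db_band, freqs_band, prominence_db = 12,
                            min_level_db = -80) {
  nb <- nrow(db_band)
  nf <- ncol(db_band)
  if (nb < 3L) stop("band spans fewer than 3 spectrogram bins")
  i <- max.col(t(db_band), ties.method = "first")
  med <- apply(db_band, 2L, stats::median)
  j <- cbind(i, seq_len(nf))
  b <- db_band[j]
  interior <- i > 1L & i < nb
  ok <- interior & (b >= med + prominence_db) & (b >= min_level_db)
  ileft <- pmax(i - 1L, 1L)
  iright <- pmin(i + 1L, nb)
  a <- db_band[cbind(ileft, seq_len(nf))]
  cc <- db_band[cbind(iright, seq_len(nf))]
  ref <- parabolic_refine(a, b, cc)
  binw <- freqs_band[2] - freqs_band[1]
  f0 <- freqs_band[i] + ifelse(interior, ref$delta, 0) * binw
  amp <- ifelse(interior, ref$value, b)
  f0[!ok] <- NA_real_
  amp[!ok] <- NA_real_
  data.frame(f0 = f0, amp = amp, present = ok)
}

#' Locate the dominant spectral peak within a frequency band
#'
#' Finds the maximum-magnitude bin inside `band` at the frame nearest `t`
#' and refines its frequency by 3-point parabolic interpolation in the dB
#' domain (sub-bin precision). The peak must stand at least
#' `prominence_db` above the band median, otherwise no tone is
#' reported (distinguishing "no flyer in band" from a tracked tone).
#'
#' @param spec A [compute_spectrogram()] result.
#' @param t Time in seconds; the nearest frame is used.
#' @param band Numeric `c(lo, hi)` in Hz, inside the spectrogram range.
#' @param prominence_db Gate above the band median (default 12 dB).
#' @param min_level_db Absolute level floor in dBFS (default -80): peaks
#'   quieter than this are window-leakage skirts or noise, not flyers.
#' @return `list(f0 = Hz, amp = dBFS)`, or `NULL` if no prominent peak.
#' @export
peak_in_band <- function(spec, t, band, prominence_db = 12,
                         min_level_db = -80) {
  stopifnot(inherits(spec, "spectrogram"), length(band) == 2L,
            band[1] < band[2])
  if (band[1] < min(spec$freqs) || band[2] > max(spec$freqs))
    stop("band outside spectrogram frequency range")
  if (t < min(spec$times) - 1e-9 || t > max(spec$times) + 1e-9)
    stop("t outside spectrogram time range")
  rows <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(rows) < 3L) stop("empty band")
  fr <- which.min(abs(spec$times - t))
  pk <- band_peaks_core(spec$db[rows, fr, drop = FALSE], spec$freqs[rows],
                        prominence_db, min_level_db)
  if (!pk$present[1]) return(NULL)
  list(f0 = pk$f0[1], amp = pk$amp[1])
}

#' Export a spectrogram band summary as CSV
#'
#' Writes one row per frame with the interpolated peak frequency and level
#' in each requested band (the hand-off format for downstream tabulation).
#'
#' @param spec A `spectrogram`.
#' @param path Output CSV path.
#' @param bands Named list of `c(lo, hi)` bands, default the male/female
#'   fundamental search ranges.
#' @return `path`, invisibly.
#' @export
export_spectrogram_csv <- function(spec, path,
                                   bands = list(male = c(700, 1100),
                                                female = c(400, 700))) {
  out <- data.frame(t = spec$times)
  for (nm in names(bands)) {
    rows <- which(spec$freqs >= bands[[nm]][1] & spec$freqs <= bands[[nm]][2])
    pk <- band_peaks_core(spec$db[rows, , drop = FALSE], spec$freqs[rows])
    out[[paste0("f0_", nm)]] <- pk$f0
    out[[paste0("db_", nm)]] <- pk$amp
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
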