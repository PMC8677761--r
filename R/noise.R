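# Spectral-subtraction noise reduction. The profile is learned from a
# silent lead-in (recorded before mosquitoes enter the cage) and applied
# magnitude-wise with phase preserved, mirroring the background-noise
# subtraction step of the recording workflow.

#' Build a noise profile from a (nominally silent) clip
#'
#' Computes the per-bin mean and standard deviation of the STFT magnitude
#' over all frames of the clip. The profile records its STFT geometry so
#' [subtract_noise()] can verify it is applied consistently.
#'
#' @param clip An [audio_clip()] of background noise, at least 1 s long.
#' @param window_s,overlap STFT geometry (no zero padding is used: noise
#'   statistics do not need a refined bin grid).
#' @return A `noise_profile`: list with `bin_freqs` (Hz), `mean_mag`,
#'   `sd_mag` (full-scale magnitude units).
#' @export
build_noise_profile <- function(clip, window_s = 4096 / 44100,
                                overlap = 0.75) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip_duration(clip) < 1) stop("noise clip must be at least 1 s long")
  geom <- stft_geometry(clip$sample_rate, window_s, overlap, zero_pad = 1)
  frames <- frame_signal(clip$samples, geom)
  X <- stft_fft(frames, geom)
  mag <- Mod(X) * mag_scale(geom)
  n <- ncol(mag)
  mu <- rowMeans(mag)
  sdv <- if (n > 1L) sqrt(pmax(rowMeans(mag^2) - mu^2, 0) * n / (n - 1))
         else rep(0, length(mu))
  structure(list(bin_freqs = (seq_along(mu) - 1L) *
                   clip$sample_rate / geom$nfft,
                 mean_mag = mu, sd_mag = sdv),
            geom = geom, n_frames = n, class = "noise_profile")
}

#' @export
print.noise_profile <- function(x, ...) {
  cat(sprintf("<noise_profile> %d bins from %d frames, mean level %.1f dBFS\n",
              length(x$bin_freqs), attr(x, "n_frames"),
              20 * log10(max(mean(x$mean_mag), 1e-12))))
  invisible(x)
}

#' Spectral-subtraction denoising against a noise profile
#'
#' Each STFT frame magnitude is reduced by
#' `over_subtraction * (mean_mag + sd_mag)` of the profile and floored at
#' `floor` times the original magnitude (a spectral floor that avoids
#' musical-noise holes); phase is preserved. The signal is reconstructed
#' by weighted overlap-add, which is exact for any hop because the output
#' is renormalised by the accumulated squared window.
#'
#' @param clip An [audio_clip()].
#' @param profile A [build_noise_profile()] result with matching sample
#'   rate; the same STFT geometry is reused.
#' @param over_subtraction Multiplier on the profile threshold (default 1).
#' @param floor Spectral floor as a fraction of the original magnitude
#'   (default 0.02).
#' @param chunk_frames Frames processed per FFT batch (memory bound).
#' @return A denoised [audio_clip()] of identical length.
#' @export
subtract_noise <- function(clip, profile, over_subtraction = 1,
                           floor = 0.02, chunk_frames = 4000L) {
  stopifnot(inherits(clip, "audio_clip"), inherits(profile, "noise_profile"))
  geom <- attr(profile, "geom")
  if (geom$sample_rate != clip$sample_rate)
    stop("profile sample rate does not match clip (STFT geometry mismatch)")
  W <- geom$W; hop <- geom$hop; nfft <- geom$nfft
  nbin <- nfft / 2 + 1L

  thr <- over_subtraction * (profile$mean_mag + profile$sd_mag) /
    mag_scale(geom)                       # back to raw |X| units
  # mirror one-sided threshold onto the full FFT grid
  thr_full <- c(thr, rev(thr[2:(nbin - 1L)]))

  x <- c(rep(0, W), clip$samples, rep(0, W))
  N <- length(x)
  starts <- seq(1L, N - W + 1L, by = hop)
  y <- numeric(N)
  wacc <- numeric(N)
  w <- geom$window
  w2 <- w^2

  for (c0 in seq(1L, length(starts), by = chunk_frames)) {
    c1 <- min(c0 + chunk_frames - 1L, length(starts))
    st <- starts[c0:c1]
    frames <- frame_signal(x, geom, starts = st)
    X <- stft_fft(frames, geom, onesided = FALSE)
    rawmag <- Mod(X)
    newmag <- pmax(rawmag - thr_full, floor * rawmag)
    gain <- newmag / pmax(rawmag, 1e-300)
    Y <- X * gain
    fr <- Re(stats::mvfft(Y, inverse = TRUE)) / nfft
    fr <- fr[seq_len(W), , drop = FALSE] * w
    for (k in seq_along(st)) {
      ii <- st[k]:(st[k] + W - 1L)
      y[ii] <- y[ii] + fr[, k]
      wacc[ii] <- wacc[ii] + w2
    }
  }
  nz <- wacc > 1e-12
  y[nz] <- y[nz] / wacc[nz]
  out <- y[(W + 1L):(W + length(clip$samples))]
  out <- pmax(pmin(out, 1), -1)
  audio_clip(out, clip$sample_rate)
}
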