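# Shared fixtures and independent oracles, all built in code.

# A pure tone (or sum of tones) as an audio clip.
make_tone <- function(freqs, dur = 1, sr = 44100, amps = 0.5,
                      noise_sd = 0) {
  t <- seq(0, dur - 1 / sr, by = 1 / sr)
  amps <- rep_len(amps, length(freqs))
  x <- numeric(length(t))
  for (k in seq_along(freqs)) x <- x + amps[k] * sin(2 * pi * freqs[k] * t)
  if (noise_sd > 0) x <- x + rnorm(length(t), 0, noise_sd)
  audio_clip(pmax(pmin(x, 1), -1), sr)
}

# Construct a tone track directly (frame grid dt, NA = gap).
make_track <- function(t, f0, amp, band = "male", hop = NULL) {
  hop <- hop %||% (if (length(t) > 1) t[2] - t[1] else 0.05)
  swarmtone:::new_tone_track(
    t, f0, amp, swarmtone:::resolve_band(band), hop,
    max(t) + hop)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive two-sided Fisher p: enumerate every table with the observed
# margins, probability by direct binomial-coefficient products, sum those
# no more probable than the observed table (minimum-likelihood rule).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(N, c1)
  p <- exp(logp)
  pobs <- p[ks == a]
  sum(p[p <= pobs * (1 + 1e-7)])
}

# Greedy matching of detected events against ground truth.
match_events <- function(truth, det, tol = 0.5) {
  used <- rep(FALSE, nrow(det))
  hit <- logical(nrow(truth))
  onset_err <- rep(NA_real_, nrow(truth))
  for (k in seq_len(nrow(truth))) {
    if (!nrow(det)) break
    ov <- pmin(det$offset, truth$offset[k]) -
      pmax(det$onset, truth$onset[k])
    j <- which(!used & (ov > 0 | abs(det$onset - truth$onset[k]) < tol))
    if (length(j)) {
      used[j[1]] <- TRUE
      hit[k] <- TRUE
      onset_err[k] <- abs(det$onset[j[1]] - truth$onset[k])
    }
  }
  list(sensitivity = mean(hit),
       precision = if (nrow(det)) sum(used) / nrow(det) else NA_real_,
       onset_err = onset_err)
}
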