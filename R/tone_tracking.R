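# Fundamental flight-tone tracking. Default sex bands follow the reported
# fundamentals (~550 Hz female, ~850 Hz male, roughly 300 Hz apart):
# FEMALE (400, 700) Hz, MALE (700, 1100) Hz.

SEX_BANDS <- list(male = c(700, 1100), female = c(400, 700))
SWARM_PERIODS <- c("PRE", "PEAK", "WANING", "LATE")

resolve_band <- function(band) {
  if (is.character(band)) {
    band <- match.arg(tolower(band), names(SEX_BANDS))
    return(list(name = toupper(band), range = SEX_BANDS[[band]]))
  }
  stopifnot(is.numeric(band), length(band) == 2L, band[1] < band[2])
  list(name = "CUSTOM", range = as.numeric(band))
}

new_tone_track <- function(t, f0, amp, band, hop_s, duration_s,
                           max_jump = 150) {
  seg <- integer(length(t))
  present <- !is.na(f0)
  if (any(present)) {
    ip <- which(present)
    brk <- c(TRUE, abs(diff(f0[ip])) > max_jump | diff(ip) > 1L)
    seg[ip] <- cumsum(brk)
  }
  structure(data.frame(t = t, f0 = f0, amp = amp, segment = seg),
            band = band$name, band_range = band$range, hop_s = hop_s,
            duration_s = duration_s, max_jump = max_jump,
            class = c("tone_track", "data.frame"))
}

#' Track the fundamental tone of one sex band through a spectrogram
#'
#' For every spectrogram frame, records the interpolated in-band peak
#' where [peak_in_band()] finds a prominent tone and a gap (`NA`) where it
#' does not. Frequency jumps larger than `max_jump` between consecutive
#' tracked frames start a new segment (distinct flyers).
#'
#' @param spec A [compute_spectrogram()] result covering the band.
#' @param band `"male"`, `"female"`, or a numeric `c(lo, hi)` range in Hz.
#' @param max_jump Continuity gate in Hz (default 150).
#' @param prominence_db Peak prominence gate (default 12 dB).
#' @param min_level_db Absolute level floor in dBFS (default -80).
#' @return A `tone_track`: data frame with one row per frame (`t`, `f0`,
#'   `amp`, `segment`; `f0`/`amp` are `NA` in gaps).
#' @export
track_band <- function(spec, band, max_jump = 150, prominence_db = 12,
                       min_level_db = -80) {
  stopifnot(inherits(spec, "spectrogram"))
  bd <- resolve_band(band)
  rows <- which(spec$freqs >= bd$range[1] & spec$freqs <= bd$range[2])
  if (length(rows) < 3L) stop("spectrogram does not cover the band")
  pk <- band_peaks_core(spec$db[rows, , drop = FALSE], spec$freqs[rows],
                        prominence_db, min_level_db)
  geom <- attr(spec, "geom")
  hop_s <- geom$hop / geom$sample_rate
  new_tone_track(spec$times, pk$f0, pk$amp, bd, hop_s,
                 max(spec$times) + hop_s, max_jump)
}

#' @export
print.tone_track <- function(x, ...) {
  n <- sum(!is.na(x$f0))
  cat(sprintf(
    "<tone_track> band %s (%g-%g Hz): %d/%d frames tracked over %.1f s\n",
    attr(x, "band"), attr(x, "band_range")[1], attr(x, "band_range")[2],
    n, nrow(x), attr(x, "duration_s")))
  invisible(x)
}

#' Track a long recording in memory-bounded chunks
#'
#' Equivalent to `track_band(compute_spectrogram(clip, ...), band)` but
#' processes the STFT in chunks along a single global frame grid, so
#' hour-long recordings are tracked without materialising the full
#' spectrogram.
#'
#' @inheritParams track_band
#' @param clip An [audio_clip()].
#' @param window_s,overlap,zero_pad STFT geometry (see
#'   [compute_spectrogram()]).
#' @param chunk_s Approximate chunk length in seconds (default 60).
#' @return A `tone_track` over the whole clip.
#' @export
track_recording <- function(clip, band, window_s = 4096 / 44100,
                            overlap = 0.75, zero_pad = 4, chunk_s = 60,
                            max_jump = 150, prominence_db = 12,
                            min_level_db = -80) {
  stopifnot(inherits(clip, "audio_clip"))
  bd <- resolve_band(band)
  geom <- stft_geometry(clip$sample_rate, window_s, overlap, zero_pad)
  N <- length(clip$samples)
  if (N < geom$W) stop("clip shorter than one analysis window")
  starts <- seq(1L, N - geom$W + 1L, by = geom$hop)
  freqs <- (0:(geom$nfft / 2)) * clip$sample_rate / geom$nfft
  rows <- which(freqs >= bd$range[1] & freqs <= bd$range[2])
  if (length(rows) < 3L) stop("band not covered at this sample rate")

  per_chunk <- max(1L, floor(chunk_s * clip$sample_rate / geom$hop))
  nf <- length(starts)
  f0 <- rep(NA_real_, nf)
  amp <- rep(NA_real_, nf)
  for (c0 in seq(1L, nf, by = per_chunk)) {
    c1 <- min(c0 + per_chunk - 1L, nf)
    frames <- frame_signal(clip$samples, geom, starts = starts[c0:c1])
    X <- stft_fft(frames, geom)
    db <- 20 * log10(pmax(Mod(X[rows, , drop = FALSE]) * mag_scale(geom),
                          10^(DB_FLOOR / 20)))
    pk <- band_peaks_core(db, freqs[rows], prominence_db, min_level_db)
    f0[c0:c1] <- pk$f0
    amp[c0:c1] <- pk$amp
  }
  times <- (starts - 1L + geom$W / 2) / clip$sample_rate
  hop_s <- geom$hop / clip$sample_rate
  new_tone_track(times, f0, amp, bd, hop_s, N / clip$sample_rate, max_jump)
}

#' Swarm period of a time point
#'
#' The 1-h swarm sequence splits into pre-swarm (0-15 min, dusk), peak
#' (15-30), waning (30-45) and late (45-60 min) periods. Bins are
#' half-open `[lo, hi)`, so t = 900 s belongs to PEAK.
#'
#' @param t Time(s) in seconds from recording start; must lie in
#'   `[0, 3600)`.
#' @return Factor with levels `PRE`, `PEAK`, `WANING`, `LATE`.
#' @examples
#' swarm_period_of(c(600, 900, 3599))
#' @export
swarm_period_of <- function(t) {
  if (any(t < 0 | t >= 3600)) stop("t must lie in [0, 3600) seconds")
  cut(t, breaks = c(0, 900, 1800, 2700, 3600), labels = SWARM_PERIODS,
      right = FALSE)
}

#' Sample a tone track on a fixed cadence
#'
#' Takes one sample at each `t = t0 + k * interval` inside the recording,
#' snapping to the nearest tracked frame within `snap` seconds; grid
#' points with no tracked frame nearby are kept as absent markers. Each
#' sample carries its swarm-period label (for t < 3600 s).
#'
#' @param track A `tone_track`.
#' @param interval Sampling cadence in seconds (default 60).
#' @param t0 First grid point (default 0).
#' @param snap Maximum snap distance in seconds (default 2).
#' @return Data frame `t`, `f0`, `amp`, `present`, `period`, `band`.
#' @export
sample_track <- function(track, interval = 60, t0 = 0, snap = 2) {
  stopifnot(inherits(track, "tone_track"), interval > 0)
  dur <- attr(track, "duration_s")
  ts <- seq(t0, by = interval,
            length.out = max(0L, floor((dur - t0 - 1e-9) / interval) + 1L))
  good <- which(!is.na(track$f0))
  f0 <- rep(NA_real_, length(ts))
  amp <- rep(NA_real_, length(ts))
  if (length(good)) {
    for (k in seq_along(ts)) {
      d <- abs(track$t[good] - ts[k])
      j <- which.min(d)
      if (d[j] <= snap) {
        f0[k] <- track$f0[good[j]]
        amp[k] <- track$amp[good[j]]
      }
    }
  }
  period <- factor(rep(NA_character_, length(ts)), levels = SWARM_PERIODS)
  in_hour <- ts >= 0 & ts < 3600
  period[in_hour] <- swarm_period_of(ts[in_hour])
  data.frame(t = ts, f0 = f0, amp = amp, present = !is.na(f0),
             period = period, band = attr(track, "band"))
}

#' Partition cadence samples by swarm period
#'
#' @param samples A [sample_track()] data frame (rows carry `period`).
#' @return Named list `PRE`, `PEAK`, `WANING`, `LATE` of sample subsets;
#'   every input row with a period label appears in exactly one bin.
#' @export
bin_by_period <- function(samples) {
  stopifnot(is.data.frame(samples), "period" %in% names(samples))
  lapply(stats::setNames(nm = SWARM_PERIODS), function(p) {
    samples[!is.na(samples$period) & samples$period == p, , drop = FALSE]
  })
}

#' Per-period summary of a tone track
#'
#' Mean and SD of frequency and amplitude per swarm period over all
#' tracked frames, optionally excluding detected interaction events (so
#' baseline swarming statistics are not inflated by mating excursions).
#'
#' @param track A `tone_track`.
#' @param events Optional [detect_events()] result; frames within
#'   `margin` s of an event span are excluded.
#' @param margin Exclusion margin around events in seconds (default 0.25).
#' @return Data frame with one row per period: `period`, `n`, `mean_f0`,
#'   `sd_f0`, `mean_amp`, `sd_amp`.
#' @export
summarize_periods <- function(track, events = NULL, margin = 0.25) {
  stopifnot(inherits(track, "tone_track"))
  keep <- !is.na(track$f0) & track$t < 3600
  if (!is.null(events) && nrow(events)) {
    for (k in seq_len(nrow(events))) {
      keep <- keep & !(track$t >= events$onset[k] - margin &
                         track$t <= events$offset[k] + margin)
    }
  }
  tt <- track[keep, , drop = FALSE]
  per <- swarm_period_of(tt$t)
  do.call(rbind, lapply(SWARM_PERIODS, function(p) {
    s <- tt[per == p, , drop = FALSE]
    data.frame(period = p, n = nrow(s),
               mean_f0 = if (nrow(s)) mean(s$f0) else NA_real_,
               sd_f0 = if (nrow(s) > 1) stats::sd(s$f0) else NA_real_,
               mean_amp = if (nrow(s)) mean(s$amp) else NA_real_,
               sd_amp = if (nrow(s) > 1) stats::sd(s$amp) else NA_real_)
  }))
}

#' Write a tone track to CSV
#' @param track A `tone_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}
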