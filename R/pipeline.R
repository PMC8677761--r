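# End-to-end recording analysis: noise profile from the silent lead-in,
# optional spectral subtraction, per-sex tone tracking, interaction
# detection and cadence sampling.

#' Analyze a swarm recording
#'
#' Runs the full pipeline on a recording (or a [simulate_swarm()] result):
#' builds the noise profile from the silent lead-in, optionally denoises,
#' tracks the male and female fundamental bands, detects
#' mating-interaction tone events in the male track, samples both tracks
#' on the 60 s cadence, bins by swarm period and summarises. All times in
#' the result are relative to the end of the lead-in (swarm time).
#'
#' @param x An [audio_clip()] or a `swarm_sim`.
#' @param lead_in_s Length of the silent lead-in at the head of the
#'   recording (default 10 s; taken from the simulation when `x` is one).
#' @param denoise Apply spectral subtraction with the lead-in profile
#'   (default TRUE).
#' @param window_s,overlap,zero_pad STFT geometry.
#' @param interval Sampling cadence in seconds (default 60).
#' @param ... Further arguments to [detect_events()].
#' @return A `swarm_analysis` list: `male_track`, `female_track`,
#'   `events`, `samples` (per sex, with period bins), `period_summary`
#'   (per sex), `noise_profile`.
#' @export
analyze_swarm <- function(x, lead_in_s = 10, denoise = TRUE,
                          window_s = 4096 / 44100, overlap = 0.75,
                          zero_pad = 4, interval = 60, ...) {
  if (inherits(x, "swarm_sim")) {
    lead_in_s <- x$lead_in_s
    clip <- x$clip
  } else clip <- x
  stopifnot(inherits(clip, "audio_clip"))

  profile <- NULL
  if (lead_in_s >= 1) {
    profile <- build_noise_profile(clip_slice(clip, 0, lead_in_s),
                                   window_s, overlap)
  }
  swarm <- if (lead_in_s > 0)
    clip_slice(clip, lead_in_s, clip_duration(clip)) else clip
  if (denoise) {
    if (is.null(profile)) stop("denoising requires a lead-in of >= 1 s")
    swarm <- subtract_noise(swarm, profile)
  }

  male_track <- track_recording(swarm, "male", window_s, overlap, zero_pad)
  female_track <- track_recording(swarm, "female", window_s, overlap,
                                  zero_pad)
  events <- detect_events(male_track, ...)

  samples <- list(
    male = sample_track(male_track, interval = interval),
    female = sample_track(female_track, interval = interval))
  binned <- lapply(samples, bin_by_period)
  period_summary <- list(
    male = summarize_periods(male_track, events),
    female = summarize_periods(female_track))

  structure(list(male_track = male_track, female_track = female_track,
                 events = events, samples = samples, binned = binned,
                 period_summary = period_summary,
                 noise_profile = profile, lead_in_s = lead_in_s),
            class = "swarm_analysis")
}

#' @export
print.swarm_analysis <- function(x, ...) {
  cat(sprintf(
    "<swarm_analysis> %d interaction events; male/female frames tracked: %d/%d\n",
    nrow(x$events), sum(!is.na(x$male_track$f0)),
    sum(!is.na(x$female_track$f0))))
  invisible(x)
}

#' Sample interactions on the 5-min cadence and classify outcomes
#'
#' Mirrors the mixed-sex assay: at each sampling time point (every 5 min
#' through the swarming portion of the sequence), takes the first segment
#' of the nearest interaction, splits it into EARLY/LATE phases, computes
#' the phase-level harmonic outcome at the best of the four ratios
#' against the female track, and assigns the outcome scenario. Time
#' points with no interaction nearby fall in the > 50 Hz scenario.
#'
#' @param analysis A [analyze_swarm()] result.
#' @param times Sampling time points in seconds (default every 300 s from
#'   900 to 3600).
#' @return Data frame `t`, `present`, `early_cat`, `late_cat`, `ratio`,
#'   `scenario`, `period`.
#' @export
sampled_interactions <- function(analysis,
                                 times = seq(900, 3600, by = 300)) {
  stopifnot(inherits(analysis, "swarm_analysis"))
  fem <- analysis$female_track
  fem_good <- which(!is.na(fem$f0))
  rows <- lapply(times, function(tp) {
    ev <- first_segment_near(analysis$events, tp)
    period <- swarm_period_of(min(tp, 3599.99))
    if (is.null(ev)) {
      return(data.frame(t = tp, present = FALSE,
                        early_cat = factor("GT50", DIFF_LEVELS),
                        late_cat = factor("GT50", DIFF_LEVELS),
                        ratio = NA_character_,
                        scenario = scenario_mixed(NA, NA),
                        period = period))
    }
    seg <- segment_phases(ev, analysis$male_track, mode = "mixed")
    out <- lapply(c("EARLY", "LATE"), function(ph) {
      pts <- seg$phase_points[seg$phase_points$phase == ph, ]
      fpts <- if (length(fem_good)) {
        vapply(pts$t, function(tt)
          fem$f0[fem_good[which.min(abs(fem$t[fem_good] - tt))]],
          numeric(1))
      } else rep(NA_real_, nrow(pts))
      phase_outcome(pts$f0, fpts)
    })
    data.frame(t = tp, present = TRUE,
               early_cat = out[[1]]$category, late_cat = out[[2]]$category,
               ratio = out[[1]]$ratio %||% NA_character_,
               scenario = scenario_mixed(out[[1]]$category,
                                         out[[2]]$category),
               period = period)
  })
  do.call(rbind, rows)
}
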