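# Artificial swarm-tone playback stimuli: 15 min of silence followed by
# 45 min of alternating 5 s periods of baseline and mating-interaction
# tone (female 550/600 Hz, male 850/900 Hz), each a sine fundamental with
# stacked harmonic overtones.

#' Canonical playback schedule
#'
#' @param sex `"female"` (baseline 550 Hz, interaction 600 Hz) or
#'   `"male"` (850/900 Hz).
#' @param silence_s Leading silence in seconds (default 900).
#' @param alternating_s Alternating block length in seconds (default
#'   2700); must be divisible by `period_s`.
#' @param period_s Length of one tone period in seconds (default 5).
#' @param baseline_hz,interaction_hz Override the per-sex defaults.
#' @param n_harmonics Number of stacked harmonics incl. the fundamental
#'   (default 5, i.e. F1-F5).
#' @return A `playback_schedule` list. Periods alternate starting with the
#'   baseline tone.
#' @examples
#' sched <- make_schedule("female")
#' count_periods(sched)   # 270 baseline + 270 interaction
#' @export
make_schedule <- function(sex = c("female", "male"), silence_s = 900,
                          alternating_s = 2700, period_s = 5,
                          baseline_hz = NULL, interaction_hz = NULL,
                          n_harmonics = 5L) {
  sex <- match.arg(sex)
  if (alternating_s %% period_s != 0)
    stop("'alternating_s' must be divisible by 'period_s'")
  if (silence_s < 0 || period_s <= 0) stop("invalid schedule durations")
  defaults <- list(female = c(550, 600), male = c(850, 900))[[sex]]
  structure(list(sex = sex,
                 silence_s = silence_s,
                 alternating_s = alternating_s,
                 period_s = period_s,
                 baseline_hz = baseline_hz %||% defaults[1],
                 interaction_hz = interaction_hz %||% defaults[2],
                 n_harmonics = as.integer(n_harmonics)),
            class = "playback_schedule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.playback_schedule <- function(x, ...) {
  np <- count_periods(x)
  cat(sprintf(
    "<playback_schedule> %s: %g s silence + %g s alternating %g s periods\n",
    x$sex, x$silence_s, x$alternating_s, x$period_s))
  cat(sprintf("  baseline %g Hz (%d periods), interaction %g Hz (%d periods), F1-F%d\n",
              x$baseline_hz, np[["n_baseline"]], x$interaction_hz,
              np[["n_interaction"]], x$n_harmonics))
  invisible(x)
}

#' Count baseline and interaction periods of a schedule
#'
#' @param schedule A [make_schedule()] result.
#' @return Named numeric `c(n_baseline, n_interaction)`; their sum is
#'   `alternating_s / period_s` exactly (baseline first).
#' @export
count_periods <- function(schedule) {
  stopifnot(inherits(schedule, "playback_schedule"))
  n <- schedule$alternating_s / schedule$period_s
  c(n_baseline = ceiling(n / 2), n_interaction = floor(n / 2))
}

#' Harmonic overtone amplitude stack
#'
#' @param n Number of harmonics.
#' @param weights Optional amplitude multipliers per overtone index
#'   (weight 1 for the fundamental); defaults to a `1/k` rolloff.
#' @return A `harmonic_stack` numeric vector.
#' @export
harmonic_stack <- function(n = 5L, weights = NULL) {
  if (is.null(weights)) weights <- 1 / seq_len(n)
  if (length(weights) != n) stop("need one weight per harmonic")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (abs(weights[1] - 1) > 1e-12) stop("the fundamental's weight must be 1")
  structure(as.numeric(weights), class = "harmonic_stack")
}

#' Render a playback schedule to audio
#'
#' Silence is exactly zero; each tone period is a phase-continuous sum of
#' sine overtones `k * f` for `k = 1..n_harmonics` with the stack weights,
#' with 10 ms raised-cosine ramps at the period boundaries (phase resets
#' at each boundary). The result is peak-normalised to -3 dBFS.
#'
#' @param schedule A [make_schedule()] result.
#' @param stack A [harmonic_stack()]; defaults to `1/k` rolloff of the
#'   schedule's `n_harmonics`.
#' @param sample_rate Output rate in Hz (default 44100). The highest
#'   overtone must stay below Nyquist.
#' @param ramp_s Boundary ramp length in seconds (default 0.010).
#' @return An [audio_clip()].
#' @export
render_playback <- function(schedule, stack = NULL, sample_rate = 44100,
                            ramp_s = 0.010) {
  stopifnot(inherits(schedule, "playback_schedule"))
  if (is.null(stack)) stack <- harmonic_stack(schedule$n_harmonics)
  nh <- length(stack)
  if (nh * schedule$interaction_hz >= sample_rate / 2)
    stop("aliasing: highest overtone at or above Nyquist")
  sr <- sample_rate
  np <- sum(count_periods(schedule))
  plen <- round(schedule$period_s * sr)
  tt <- (seq_len(plen) - 1L) / sr
  nr <- round(ramp_s * sr)
  env <- rep(1, plen)
  if (nr > 0L) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 0.5) / nr)
    env[seq_len(nr)] <- ramp
    env[plen - nr + seq_len(nr)] <- rev(ramp)
  }
  tone_for <- function(f) {
    s <- numeric(plen)
    for (k in seq_len(nh)) s <- s + stack[k] * sin(2 * pi * k * f * tt)
    s * env
  }
  base_tone <- tone_for(schedule$baseline_hz)
  int_tone <- tone_for(schedule$interaction_hz)
  x <- numeric(round((schedule$silence_s + schedule$alternating_s) * sr))
  off <- round(schedule$silence_s * sr)
  for (p in seq_len(np)) {
    seg <- if (p %% 2L == 1L) base_tone else int_tone
    x[off + (p - 1L) * plen + seq_len(plen)] <- seg
  }
  x <- x / max(abs(x)) * 10^(-3 / 20)
  audio_clip(x, sr)
}

#' Playback sampling plan counts
#'
#' Per trial: one tone sample per minute of silence plus one per minute in
#' each of the two alternating period types (15 + 90 = 105 with the
#' defaults), and one presence/absence assay per alternating period (540
#' with the defaults). Totals scale with the number of trials.
#'
#' @param schedule A [make_schedule()] result.
#' @param n_trials Number of trials (default 3).
#' @return Named numeric `c(tone_samples, period_assays)`.
#' @examples
#' sampling_plan(make_schedule("female"))       # 315 and 1620
#' sampling_plan(make_schedule("female"), 1)    # 105 and 540
#' @export
sampling_plan <- function(schedule, n_trials = 3) {
  stopifnot(inherits(schedule, "playback_schedule"), n_trials >= 0)
  per_trial_tone <- schedule$silence_s / 60 + 2 * (schedule$alternating_s / 60)
  per_trial_assay <- sum(count_periods(schedule))
  c(tone_samples = per_trial_tone * n_trials,
    period_assays = per_trial_assay * n_trials)
}

#' Classify every playback period from audio
#'
#' For each alternating period of the schedule, measures the fundamental
#' at the period midpoint with [peak_in_band()] and assigns the period to
#' whichever of the baseline/interaction frequencies is closer. Used for
#' round-trip validation of rendered stimuli.
#'
#' @param clip An [audio_clip()] containing the rendered (or recorded)
#'   playback.
#' @param schedule The [make_schedule()] that generated it.
#' @param window_s STFT window (default 4096/44100 s).
#' @return Data frame `period`, `t_mid`, `true_type`, `f0`, `est_type`,
#'   `correct`.
#' @export
classify_playback_periods <- function(clip, schedule,
                                      window_s = 4096 / 44100) {
  stopifnot(inherits(clip, "audio_clip"),
            inherits(schedule, "playback_schedule"))
  sr <- clip$sample_rate
  np <- sum(count_periods(schedule))
  half_band <- abs(schedule$interaction_hz - schedule$baseline_hz) * 2
  band <- c(min(schedule$baseline_hz, schedule$interaction_hz) - half_band,
            max(schedule$baseline_hz, schedule$interaction_hz) + half_band)
  W <- round(window_s * sr)
  out <- data.frame(period = seq_len(np),
                    t_mid = schedule$silence_s +
                      (seq_len(np) - 0.5) * schedule$period_s,
                    true_type = ifelse(seq_len(np) %% 2L == 1L,
                                       "baseline", "interaction"),
                    f0 = NA_real_, est_type = NA_character_)
  for (p in seq_len(np)) {
    mid <- round(out$t_mid[p] * sr)
    i0 <- mid - W %/% 2L
    seg <- audio_clip(clip$samples[i0:(i0 + W + 1L)], sr)
    sp <- compute_spectrogram(seg, window_s = window_s, overlap = 0)
    pk <- peak_in_band(sp, sp$times[1], band)
    if (!is.null(pk)) {
      out$f0[p] <- pk$f0
      out$est_type[p] <- if (abs(pk$f0 - schedule$baseline_hz) <=
                               abs(pk$f0 - schedule$interaction_hz))
        "baseline" else "interaction"
    }
  }
  out$correct <- !is.na(out$est_type) & out$est_type == out$true_type
  out
}
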