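# Seeded synthetic swarm audio with ground truth. Individual wingbeat
# trajectories are mean-reverting (Ornstein-Uhlenbeck) walks around a
# sex- and period-dependent mean, each individual contributing a stack of
# harmonic overtones (4 male, 5 female). Mating-interaction events add a
# frequency step, an amplitude step and sinusoidal rapid frequency
# modulation with raised-cosine onsets. A silent (noise-only) lead-in
# precedes the swarm for noise profiling.

#' Synthetic swarm configuration
#'
#' Defaults emulate the recorded study conditions: a 30:10 male:female
#' swarm, male baseline fundamental near 843 Hz and female near 550 Hz,
#' swarm participation rising from the pre-swarm to the peak period and
#' declining thereafter, interaction events with +50-60 Hz frequency and
#' +10-24 dB amplitude excursions plus rapid FM, and broadband background
#' noise with a 10 s silent lead-in.
#'
#' @param n_males,n_females Individuals per sex (default 30 and 10, the
#'   3:1 mixed-swarm sex ratio).
#' @param male_base_hz,female_base_hz Baseline fundamentals (843, 550 Hz).
#' @param male_period_offset_hz,female_period_offset_hz Named per-period
#'   frequency offsets (PRE/PEAK/WANING/LATE) added to the base.
#' @param participation Named per-period probability that an individual
#'   swarms in that period.
#' @param event_rate Named per-period interaction events per minute.
#' @param n_events Optional exact total event count (overrides
#'   `event_rate` totals; events are allocated across periods in
#'   proportion to the rates).
#' @param interaction_df_hz,interaction_da_db Event excursion ranges
#'   (scalars fix the value, length-2 vectors are uniform ranges).
#' @param event_duration_s Event duration range in seconds.
#' @param fm_depth_hz,fm_rate_hz Sinusoidal rapid-FM depth and rate.
#' @param jitter_sd_hz,jitter_tau_s Stationary SD and reversion time of
#'   the per-individual frequency walk.
#' @param amp_db Per-individual fundamental level in dBFS.
#' @param amp_jitter_db,amp_tau_s Amplitude walk SD (dB) and reversion
#'   time.
#' @param male_harmonics,female_harmonics Overtones per sex (4 and 5),
#'   `1/k` amplitude rolloff.
#' @param female_bout_s Range of female "offering flight" bout lengths.
#' @param noise_db Background noise RMS in dBFS.
#' @param lead_in_s Silent (noise-only) lead-in for noise profiling.
#' @param sample_rate Synthesis rate in Hz. Default 8000, the minimum
#'   standard rate that keeps the highest modeled overtone (male fourth
#'   harmonic during interactions, ~3.8 kHz) below Nyquist.
#' @param playback Optional [make_schedule()] to mix into the audio (the
#'   playback experiment design).
#' @param playback_peak_db Peak level of the mixed playback in dBFS.
#' @param seed Integer RNG seed; identical configs and seeds give
#'   identical audio and ground truth.
#' @return A `swarm_sim_config` list.
#' @export
swarm_sim_config <- function(n_males = 30L, n_females = 10L,
                             male_base_hz = 843, female_base_hz = 550,
                             male_period_offset_hz =
                               c(PRE = -15, PEAK = 15, WANING = 0,
                                 LATE = -10),
                             female_period_offset_hz =
                               c(PRE = -10, PEAK = 10, WANING = 0,
                                 LATE = -5),
                             participation =
                               c(PRE = 0.14, PEAK = 0.58, WANING = 0.43,
                                 LATE = 0.31),
                             event_rate =
                               c(PRE = 0.25, PEAK = 2.8, WANING = 1.0,
                                 LATE = 0.4),
                             n_events = NULL,
                             interaction_df_hz = c(50, 60),
                             interaction_da_db = c(10, 24),
                             event_duration_s = c(1, 2),
                             fm_depth_hz = 40, fm_rate_hz = 6,
                             jitter_sd_hz = 15, jitter_tau_s = 2,
                             amp_db = -36, amp_jitter_db = 2,
                             amp_tau_s = 1,
                             male_harmonics = 4L, female_harmonics = 5L,
                             female_bout_s = c(3, 10),
                             noise_db = -50, lead_in_s = 10,
                             sample_rate = 8000, playback = NULL,
                             playback_peak_db = -26, seed = 1L) {
  stopifnot(n_males >= 0, n_females >= 0,
            all(participation >= 0 & participation <= 1),
            all(event_rate >= 0), sample_rate >= 8000)
  cfg <- as.list(environment())
  cfg$n_males <- as.integer(n_males)
  cfg$n_females <- as.integer(n_females)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "swarm_sim_config")
}

#' Preset: single-sex swarm of 40 individuals, no mating events
#' @param sex `"male"` or `"female"`.
#' @param ... Overrides passed to [swarm_sim_config()].
#' @return A `swarm_sim_config`.
#' @export
single_sex_config <- function(sex = c("male", "female"), ...) {
  sex <- match.arg(sex)
  args <- list(...)
  args$n_males <- if (sex == "male") 40L else 0L
  args$n_females <- if (sex == "male") 0L else 40L
  if (is.null(args$event_rate))
    args$event_rate <- c(PRE = 0, PEAK = 0, WANING = 0, LATE = 0)
  do.call(swarm_sim_config, args)
}

#' Preset: mixed-sex 30:10 swarm with period-scaled interaction rates
#' @param ... Overrides passed to [swarm_sim_config()].
#' @return A `swarm_sim_config`.
#' @export
mixed_config <- function(...) swarm_sim_config(...)

#' Preset: 40 males with an artificial female playback track mixed in
#' @param ... Overrides passed to [swarm_sim_config()].
#' @return A `swarm_sim_config` whose `playback` is the default female
#'   schedule (females are replaced by the rendered stimulus).
#' @export
playback_config <- function(...) {
  args <- list(...)
  args$n_males <- args$n_males %||% 40L
  args$n_females <- 0L
  args$playback <- args$playback %||% make_schedule("female")
  do.call(swarm_sim_config, args)
}

# OU process on a regular grid: stationary sd `sigma`, reversion time tau.
ou_path <- function(n, dt, sigma, tau) {
  if (n == 0L) return(numeric(0))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - a^2))
  x0 <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

raised_cosine_env <- function(tt, onset, offset, ramp = 0.05) {
  env <- numeric(length(tt))
  inside <- tt >= onset & tt <= offset
  env[inside] <- 1
  up <- tt >= onset & tt < onset + ramp
  env[up] <- 0.5 - 0.5 * cos(pi * (tt[up] - onset) / ramp)
  dn <- tt > offset - ramp & tt <= offset
  env[dn] <- 0.5 - 0.5 * cos(pi * (offset - tt[dn]) / ramp)
  env
}

period_index_of <- function(t) pmin(findInterval(t, c(0, 900, 1800, 2700)), 4L)

# Draw non-overlapping event spans (global 3 s separation), allocated
# across periods in proportion to event_rate.
draw_events <- function(cfg, duration_s) {
  rates <- cfg$event_rate
  pstart <- c(0, 900, 1800, 2700)
  pend <- pmin(c(900, 1800, 2700, 3600), duration_s)
  live <- which(pend > pstart)
  minutes <- pmax(pend - pstart, 0) / 60
  lambda <- rates[seq_along(minutes)] * minutes
  counts <- integer(4)
  if (!is.null(cfg$n_events)) {
    if (sum(lambda) <= 0) {
      w <- minutes / max(sum(minutes), 1e-9)
    } else w <- lambda / sum(lambda)
    counts[live] <- as.integer(stats::rmultinom(1, cfg$n_events, w[live]))
  } else {
    counts[live] <- stats::rpois(length(live), lambda[live])
  }
  ev <- NULL
  for (p in live) {
    np <- counts[p]
    if (np == 0L) next
    lo <- pstart[p] + 1; hi <- pend[p] - max(cfg$event_duration_s) - 1
    if (hi <= lo) next
    for (k in seq_len(np)) {
      for (try in 1:200) {
        on <- stats::runif(1, lo, hi)
        du <- stats::runif(1, cfg$event_duration_s[1],
                           max(cfg$event_duration_s))
        if (is.null(ev) ||
            all(on > ev$offset + 3 | on + du < ev$onset - 3)) {
          ev <- rbind(ev, data.frame(onset = on, offset = on + du,
                                     period = p))
          break
        }
      }
    }
  }
  if (is.null(ev)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      period = integer(0), male_id = integer(0),
                      female_id = integer(0), df_hz = numeric(0),
                      da_db = numeric(0)))
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  rng <- function(r) if (length(r) == 1L) rep(r, nrow(ev)) else
    stats::runif(nrow(ev), r[1], r[2])
  ev$df_hz <- rng(cfg$interaction_df_hz)
  ev$da_db <- rng(cfg$interaction_da_db)
  ev$male_id <- NA_integer_
  ev$female_id <- if (cfg$n_females > 0)
    sample.int(cfg$n_females, nrow(ev), replace = TRUE) else NA_integer_
  rownames(ev) <- NULL
  ev
}

#' Simulate seeded swarm audio with ground truth
#'
#' Deterministic for a fixed `(config, seed)`. The audio is the sum of
#' per-individual harmonic tone stacks (with per-individual OU frequency
#' and amplitude jitter and per-period participation), scheduled
#' interaction events on single males, Gaussian background noise, a
#' noise-only lead-in, and optionally a mixed-in playback stimulus. The
#' ground truth logs every injected parameter for parameter-recovery
#' tests.
#'
#' @param config A [swarm_sim_config()].
#' @param duration_s Swarm duration in seconds after the lead-in
#'   (default 3600).
#' @return A `swarm_sim` list: `clip` (the [audio_clip()], lead-in
#'   included), `truth` (list with `events`, `period_f0`,
#'   `participation`), `lead_in_s`, `config`.
#' @export
simulate_swarm <- function(config, duration_s = 3600) {
  stopifnot(inherits(config, "swarm_sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(config$seed)
  cfg <- config
  sr <- cfg$sample_rate
  dt <- 0.01
  n_total <- round((cfg$lead_in_s + duration_s) * sr)
  x <- stats::rnorm(n_total, 0, 10^(cfg$noise_db / 20))

  periods_live <- unique(period_index_of(
    seq(0, duration_s - 1e-9, by = 60)))
  np <- 4L

  events <- draw_events(cfg, duration_s)

  # per-sex activity matrices: individual x period
  act_m <- matrix(FALSE, nrow = cfg$n_males, ncol = np)
  act_f <- matrix(FALSE, nrow = cfg$n_females, ncol = np)
  for (p in periods_live) {
    if (cfg$n_males > 0)
      act_m[, p] <- stats::runif(cfg$n_males) < cfg$participation[p]
    if (cfg$n_females > 0)
      act_f[, p] <- stats::runif(cfg$n_females) < cfg$participation[p]
  }
  # assign each event a male active in its period; the amplitude step is
  # expressed relative to the background chorus level (the energy sum of
  # the period's active males), matching the "increase relative to
  # background male tones" definition of the excursion
  events$boost_db <- numeric(nrow(events))
  if (nrow(events) && cfg$n_males > 0) {
    for (k in seq_len(nrow(events))) {
      p <- events$period[k]
      cand <- which(act_m[, p])
      if (!length(cand)) {
        id <- sample.int(cfg$n_males, 1L)
        act_m[id, p] <- TRUE
      } else id <- cand[sample.int(length(cand), 1L)]
      events$male_id[k] <- id
      n_act <- max(1, sum(act_m[, p]))
      events$boost_db[k] <- events$da_db[k] + 10 * log10(n_act)
    }
  }

  # accumulators for realised per-period mean f0 (event spans excluded)
  f_sum <- matrix(0, nrow = 2L, ncol = np)  # rows: male, female
  f_cnt <- matrix(0, nrow = 2L, ncol = np)

  synth_individual <- function(base_hz, offsets, act_row, nh, sex_row,
                               my_events) {
    # maximal runs of consecutive active periods
    r <- rle(act_row)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      t0 <- (starts[j] - 1L) * 900
      t1 <- min(ends[j] * 900, duration_s)
      if (t1 <= t0) next
      synth_segment(base_hz, offsets, t0, t1, nh, sex_row, my_events)
    }
  }

  synth_segment <- function(base_hz, offsets, t0, t1, nh, sex_row,
                            my_events) {
    ng <- max(2L, round((t1 - t0) / dt))
    tg <- t0 + (seq_len(ng) - 1L) * dt
    pid <- period_index_of(tg)
    fg <- base_hz + offsets[pid] + ou_path(ng, dt, cfg$jitter_sd_hz,
                                           cfg$jitter_tau_s)
    ag <- cfg$amp_db + ou_path(ng, dt, cfg$amp_jitter_db, cfg$amp_tau_s)
    in_event <- rep(FALSE, ng)
    if (!is.null(my_events) && nrow(my_events)) {
      for (k in seq_len(nrow(my_events))) {
        on <- my_events$onset[k]; off <- my_events$offset[k]
        if (off <= t0 || on >= t1) next
        env <- raised_cosine_env(tg, on, off, ramp = 0.05)
        fg <- fg + env * (my_events$df_hz[k] +
                            cfg$fm_depth_hz *
                            sin(2 * pi * cfg$fm_rate_hz * (tg - on)))
        ag <- ag + env * my_events$boost_db[k]
        in_event <- in_event | (tg >= on & tg <= off)
      }
    }
    # realised baseline frequency bookkeeping (non-event grid points)
    for (p in unique(pid)) {
      sel <- pid == p & !in_event
      f_sum[sex_row, p] <<- f_sum[sex_row, p] + sum(fg[sel])
      f_cnt[sex_row, p] <<- f_cnt[sex_row, p] + sum(sel)
    }
    # upsample to audio rate and add the harmonic stack
    i0 <- round((cfg$lead_in_s + t0) * sr)
    ns <- round((t1 - t0) * sr)
    ts <- t0 + (seq_len(ns) - 1L) / sr
    fs <- stats::approx(tg, fg, xout = ts, rule = 2)$y
    As <- 10^(stats::approx(tg, ag, xout = ts, rule = 2)$y / 20)
    # fade segment edges over 100 ms to avoid onset clicks
    nf <- min(round(0.1 * sr), ns %/% 2L)
    if (nf > 0L) {
      fade <- 0.5 - 0.5 * cos(pi * (seq_len(nf) - 0.5) / nf)
      As[seq_len(nf)] <- As[seq_len(nf)] * fade
      As[ns - nf + seq_len(nf)] <- As[ns - nf + seq_len(nf)] * rev(fade)
    }
    phase <- 2 * pi * cumsum(fs) / sr
    seg <- numeric(ns)
    for (k in seq_len(nh)) seg <- seg + (1 / k) * sin(k * phase)
    idx <- i0 + seq_len(ns)
    x[idx] <<- x[idx] + As * seg
    invisible(NULL)
  }

  if (cfg$n_males > 0) {
    for (id in seq_len(cfg$n_males)) {
      mine <- events[!is.na(events$male_id) & events$male_id == id, ,
                     drop = FALSE]
      synth_individual(cfg$male_base_hz, cfg$male_period_offset_hz,
                       act_m[id, ], cfg$male_harmonics, 1L, mine)
    }
  }
  if (cfg$n_females > 0) {
    for (id in seq_len(cfg$n_females)) {
      # offering flight: discontinuous bouts inside active periods
      for (p in which(act_f[id, ])) {
        t0p <- (p - 1L) * 900
        t1p <- min(p * 900, duration_s)
        t <- t0p + stats::runif(1, 0, 5)
        while (t < t1p - 1) {
          bout <- stats::runif(1, cfg$female_bout_s[1], cfg$female_bout_s[2])
          b1 <- min(t + bout, t1p)
          synth_segment(cfg$female_base_hz, cfg$female_period_offset_hz,
                        t, b1, cfg$female_harmonics, 2L, NULL)
          t <- b1 + stats::runif(1, 5, 15)
        }
      }
    }
  }

  if (!is.null(cfg$playback)) {
    pb <- render_playback(cfg$playback, sample_rate = sr)
    lvl <- 10^(cfg$playback_peak_db / 20) / max(abs(pb$samples))
    i0 <- round(cfg$lead_in_s * sr)
    nmix <- min(length(pb$samples), n_total - i0)
    x[i0 + seq_len(nmix)] <- x[i0 + seq_len(nmix)] +
      pb$samples[seq_len(nmix)] * lvl
  }

  mx <- max(abs(x))
  scale <- 1
  if (mx > 0.999) {
    scale <- 0.999 / mx
    x <- x * scale
  }

  period_f0 <- data.frame(
    period = SWARM_PERIODS,
    male_mean_f0 = ifelse(f_cnt[1L, ] > 0, f_sum[1L, ] / f_cnt[1L, ],
                          NA_real_),
    female_mean_f0 = ifelse(f_cnt[2L, ] > 0, f_sum[2L, ] / f_cnt[2L, ],
                            NA_real_))
  participation <- data.frame(
    period = SWARM_PERIODS,
    n_males = colSums(act_m), n_females = colSums(act_f))
  events$period <- factor(SWARM_PERIODS[events$period],
                          levels = SWARM_PERIODS)

  structure(list(clip = audio_clip(x, sr),
                 truth = list(events = events, period_f0 = period_f0,
                              participation = participation,
                              scale = scale),
                 lead_in_s = cfg$lead_in_s,
                 config = cfg),
            class = "swarm_sim")
}

#' @export
print.swarm_sim <- function(x, ...) {
  cat(sprintf(
    "<swarm_sim> %.0f s swarm + %.0f s lead-in @ %d Hz; %d males, %d females, %d events\n",
    clip_duration(x$clip) - x$lead_in_s, x$lead_in_s,
    x$clip$sample_rate, x$config$n_males, x$config$n_females,
    nrow(x$truth$events)))
  invisible(x)
}
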