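# Mating-interaction tone detection. A male tone qualifies only when all
# three criteria hold simultaneously: (1) a >= 25 Hz frequency rise over
# background swarming males, (2) a >= 10 dB amplitude rise over background
# male tones, and (3) rapid frequency modulation (quantified here as the
# f0 standard deviation over a short window).

#' Background male tone statistics around a time point
#'
#' Medians of frequency and amplitude over non-candidate tracked frames in
#' a window centred on `t`. Candidate (putative interaction) frames are
#' excluded so the background is not contaminated by the excursion being
#' measured.
#'
#' @param track A `tone_track`.
#' @param t Centre time in seconds.
#' @param window Window length in seconds (default 20, i.e. +/- 10 s).
#' @param exclude Optional logical vector over track frames flagging
#'   interaction candidates to exclude.
#' @return `list(f_bg = Hz, a_bg = dBFS, window = s, n = frames used)`.
#' @export
background_stats <- function(track, t, window = 20, exclude = NULL) {
  stopifnot(inherits(track, "tone_track"))
  sel <- !is.na(track$f0) & track$t >= t - window / 2 &
    track$t <= t + window / 2
  if (!is.null(exclude)) sel <- sel & !exclude
  if (sum(sel) < 5L) stop("no background: fewer than 5 usable frames")
  list(f_bg = stats::median(track$f0[sel]),
       a_bg = stats::median(track$amp[sel]),
       window = window, n = sum(sel))
}

#' Test for rapid frequency modulation at a time point
#'
#' TRUE iff the standard deviation of tracked f0 within `fm_window`
#' around `t` is at least `fm_sd_min` Hz. Fewer than 4 tracked frames in
#' the window yields FALSE (not an error: sparse tracks simply cannot
#' exhibit measurable modulation).
#'
#' @param track A `tone_track`.
#' @param t Centre time in seconds.
#' @param fm_window Window length in seconds (default 0.5).
#' @param fm_sd_min Threshold in Hz (default 15).
#' @return Logical scalar.
#' @export
is_rapid_fm <- function(track, t, fm_window = 0.5, fm_sd_min = 15) {
  stopifnot(inherits(track, "tone_track"))
  sel <- !is.na(track$f0) & track$t >= t - fm_window / 2 &
    track$t <= t + fm_window / 2
  if (sum(sel) < 4L) return(FALSE)
  stats::sd(track$f0[sel]) >= fm_sd_min
}

# Rolling median over the frame grid, NA-gaps bridged by interpolation
# (gap frames get a background value but are never used as signal).
rolling_median <- function(v, k) {
  k <- max(3L, k + (1L - k %% 2L))        # odd, >= 3
  good <- !is.na(v)
  if (!any(good)) return(v)
  filled <- v
  if (any(!good))
    filled[!good] <- stats::approx(which(good), v[good], xout = which(!good),
                                   rule = 2)$y
  as.numeric(stats::runmed(filled, k, endrule = "median"))
}

# Rolling SD over a centred window of w frames, requiring >= 4 valid.
rolling_sd <- function(v, w) {
  n <- length(v)
  good <- !is.na(v)
  x <- ifelse(good, v, 0)
  cs <- cumsum(x); cs2 <- cumsum(x^2); cn <- cumsum(good)
  h <- max(1L, w %/% 2L)
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  S <- cs[hi] - c(0, cs)[lo]
  S2 <- cs2[hi] - c(0, cs2)[lo]
  m <- cn[hi] - c(0, cn)[lo]
  out <- rep(NA_real_, n)
  okn <- m >= 4L
  varr <- (S2[okn] - S[okn]^2 / m[okn]) / (m[okn] - 1L)
  out[okn] <- sqrt(pmax(varr, 0))
  out
}

#' Detect mating-interaction tone events in a male track
#'
#' Flags frames satisfying all three interaction criteria against a
#' rolling-median background, refines the background by excluding
#' first-pass candidate frames, merges qualifying runs across gaps
#' shorter than `gap_merge`, and discards runs shorter than
#' `min_duration`. Returned events are disjoint and time-ordered; events
#' separated by less than `group_gap` are labelled as segments of one
#' multi-segment interaction.
#'
#' @param track A `tone_track` (typically the male band).
#' @param df_min Minimum frequency rise in Hz (default 25).
#' @param da_min Minimum amplitude rise in dB (default 10).
#' @param min_duration Minimum event duration in seconds (default 0.5).
#' @param gap_merge Merge gap in seconds (default 0.25).
#' @param fm_window,fm_sd_min Rapid-FM quantification (default 0.5 s,
#'   15 Hz); set `fm_sd_min = 0` to drop criterion 3.
#' @param bg_window Background window in seconds (default 20).
#' @param group_gap Segment grouping gap in seconds (default 2).
#' @return An `interaction_events` data frame: `onset`, `offset`,
#'   `duration`, `interaction_id`, `segment_index`, `peak_f0`, `peak_amp`,
#'   `n_frames`.
#' @export
detect_events <- function(track, df_min = 25, da_min = 10,
                          min_duration = 0.5, gap_merge = 0.25,
                          fm_window = 0.5, fm_sd_min = 15,
                          bg_window = 20, group_gap = 2) {
  stopifnot(inherits(track, "tone_track"))
  empty <- structure(
    data.frame(onset = numeric(0), offset = numeric(0),
               duration = numeric(0), interaction_id = integer(0),
               segment_index = integer(0), peak_f0 = numeric(0),
               peak_amp = numeric(0), n_frames = integer(0)),
    class = c("interaction_events", "data.frame"))
  good <- !is.na(track$f0)
  if (!any(good)) return(empty)
  hop <- attr(track, "hop_s")
  kbg <- round(bg_window / hop)
  f_bg <- rolling_median(track$f0, kbg)
  a_bg <- rolling_median(track$amp, kbg)

  # first pass: excursion candidates against the plain rolling median
  cand <- good & (track$f0 - f_bg >= df_min) & (track$amp - a_bg >= da_min)

  # second pass: re-estimate background near candidate runs, excluding
  # candidate frames (medians are robust, but long events could bias them)
  runs <- rle(as.vector(cand))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    lo <- max(1L, starts[r] - kbg %/% 2L)
    hi <- min(nrow(track), ends[r] + kbg %/% 2L)
    sel <- lo:hi
    bgsel <- sel[good[sel] & !cand[sel]]
    if (length(bgsel) >= 5L) {
      f_bg[sel] <- stats::median(track$f0[bgsel])
      a_bg[sel] <- stats::median(track$amp[bgsel])
    }
  }
  crit1 <- good & (track$f0 - f_bg >= df_min)
  crit2 <- good & (track$amp - a_bg >= da_min)
  crit3 <- if (fm_sd_min > 0) {
    sdv <- rolling_sd(track$f0, round(fm_window / hop))
    good & !is.na(sdv) & sdv >= fm_sd_min
  } else good
  cond <- crit1 & crit2 & crit3

  idx <- which(cond)
  if (!length(idx)) return(empty)
  tt <- track$t[idx]
  newrun <- c(TRUE, diff(tt) > gap_merge + hop / 2)
  rid <- cumsum(newrun)
  onset <- as.numeric(tapply(tt, rid, min))
  offset <- as.numeric(tapply(tt, rid, max)) + hop
  keep <- (offset - onset) >= min_duration
  if (!any(keep)) return(empty)
  onset <- onset[keep]; offset <- offset[keep]
  ev <- data.frame(onset = onset, offset = offset,
                   duration = offset - onset)
  ev <- ev[order(ev$onset), , drop = FALSE]
  gid <- cumsum(c(TRUE, ev$onset[-1] - ev$offset[-nrow(ev)] > group_gap))
  ev$interaction_id <- gid
  ev$segment_index <- stats::ave(seq_len(nrow(ev)), gid,
                                 FUN = seq_along)
  ev$peak_f0 <- vapply(seq_len(nrow(ev)), function(k) {
    s <- good & track$t >= ev$onset[k] & track$t <= ev$offset[k]
    max(track$f0[s])
  }, numeric(1))
  ev$peak_amp <- vapply(seq_len(nrow(ev)), function(k) {
    s <- good & track$t >= ev$onset[k] & track$t <= ev$offset[k]
    max(track$amp[s])
  }, numeric(1))
  ev$n_frames <- vapply(seq_len(nrow(ev)), function(k) {
    sum(cond & track$t >= ev$onset[k] & track$t <= ev$offset[k])
  }, integer(1))
  rownames(ev) <- NULL
  structure(ev, class = c("interaction_events", "data.frame"))
}

#' Segment an interaction event into sampling phases
#'
#' In mixed-sex mode the event span (minus a short drop-out trim at the
#' end, when the couple falls from the swarm) is halved into EARLY and
#' LATE phases. In playback mode the phases are BEFORE (the 1.5 s of
#' background male tone preceding onset) and DURING (the event span).
#' Each phase is sampled at three time points at 10%, 50% and 90% of its
#' span, snapped to the nearest tracked frame; phases too short for three
#' distinct frames reuse the nearest frames and set `low_resolution`.
#'
#' @param event One row of a [detect_events()] result (or a list with
#'   `onset`/`offset`).
#' @param track The `tone_track` the event was detected in.
#' @param mode `"mixed"` (EARLY/LATE) or `"playback"` (BEFORE/DURING).
#' @param drop_trim_max Maximum end trim in seconds (the trim is
#'   `min(drop_trim_max, 10%` of duration`)`; default 0.2).
#' @param before_s BEFORE-phase length for playback mode (default 1.5).
#' @return The event as a list with `phase_points` (data frame `phase`,
#'   `t`, `f0`, `amp`) and `low_resolution` flag added.
#' @export
segment_phases <- function(event, track, mode = c("mixed", "playback"),
                           drop_trim_max = 0.2, before_s = 1.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "tone_track"))
  onset <- event$onset
  offset <- event$offset
  dur <- offset - onset
  trim <- min(drop_trim_max, 0.10 * dur)
  spans <- if (mode == "mixed") {
    mid <- onset + (dur - trim) / 2
    list(EARLY = c(onset, mid), LATE = c(mid, offset - trim))
  } else {
    list(BEFORE = c(onset - before_s, onset),
         DURING = c(onset, offset - trim))
  }
  good <- which(!is.na(track$f0))
  low_res <- FALSE
  pts <- do.call(rbind, lapply(names(spans), function(ph) {
    sp <- spans[[ph]]
    targets <- sp[1] + c(0.1, 0.5, 0.9) * (sp[2] - sp[1])
    rows <- vapply(targets, function(tg) {
      good[which.min(abs(track$t[good] - tg))]
    }, integer(1))
    if (length(unique(rows)) < 3L) low_res <<- TRUE
    data.frame(phase = ph, t = track$t[rows], f0 = track$f0[rows],
               amp = track$amp[rows])
  }))
  out <- as.list(event)
  out$phase_points <- pts
  out$low_resolution <- low_res
  out$mode <- mode
  out
}

#' First segment of the interaction nearest a sampling time point
#'
#' Among interactions (segment groups) overlapping or nearest to `t`,
#' returns the first segment of the temporally closest interaction, or
#' `NULL` if none lies within `radius` seconds (half the 5-min sampling
#' cadence by default).
#'
#' @param events A [detect_events()] result.
#' @param t Sampling time point in seconds.
#' @param radius Search radius in seconds (default 150).
#' @return One event row (data frame), or `NULL`.
#' @export
first_segment_near <- function(events, t, radius = 150) {
  if (is.null(events) || nrow(events) == 0L) return(NULL)
  dist_of <- function(rows) {
    lo <- min(rows$onset); hi <- max(rows$offset)
    if (t >= lo && t <= hi) 0 else min(abs(t - lo), abs(t - hi))
  }
  ids <- unique(events$interaction_id)
  d <- vapply(ids, function(id)
    dist_of(events[events$interaction_id == id, , drop = FALSE]),
    numeric(1))
  j <- which.min(d)
  if (d[j] > radius) return(NULL)
  grp <- events[events$interaction_id == ids[j], , drop = FALSE]
  grp[which.min(grp$segment_index), , drop = FALSE]
}
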