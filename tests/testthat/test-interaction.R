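# Constructed tracks: a steady 850 Hz background with controlled
# excursions, at a 0.05 s frame grid.

flat_track <- function(dur = 60, f = 850, a = -30, dt = 0.05,
                       jitter_f = 0, jitter_a = 0, seed = 1) {
  t <- seq(0, dur - dt, by = dt)
  withr::with_seed(seed, {
    make_track(t, f + rnorm(length(t), 0, jitter_f),
               a + rnorm(length(t), 0, jitter_a))
  })
}

# add an excursion with optional sinusoidal FM over [on, off]; the FM
# rate must not sit at the frame-grid Nyquist (10 Hz at dt = 0.05)
with_event <- function(tr, on, off, df = 50, da = 15, fm_depth = 40,
                       fm_rate = 7) {
  sel <- tr$t >= on & tr$t <= off
  tr$f0[sel] <- tr$f0[sel] + df +
    fm_depth * sin(2 * pi * fm_rate * (tr$t[sel] - on))
  tr$amp[sel] <- tr$amp[sel] + da
  tr
}

test_that("background statistics are robust medians", {
  tr <- flat_track()
  bg <- background_stats(tr, 30)
  expect_equal(bg$f_bg, 850, tolerance = 1e-6)
  expect_equal(bg$a_bg, -30, tolerance = 1e-6)

  # a 2 s excursion inside the 20 s window barely moves the median
  tr2 <- with_event(tr, 29, 31, df = 50, da = 0, fm_depth = 0)
  expect_lt(abs(background_stats(tr2, 30)$f_bg - 850), 1)

  # empty window
  empty <- flat_track(dur = 2)
  expect_error(background_stats(empty, 100), "no background")
})

test_that("rapid FM is an f0 dispersion gate", {
  tr <- flat_track()
  expect_false(is_rapid_fm(tr, 30))
  # +/-40 Hz sinusoidal FM at 10 Hz: sampled SD ~ 28 Hz > 15
  # (frame grid at 0.02 s so the 10 Hz modulation is well sampled)
  trfm10 <- with_event(flat_track(dt = 0.02), 20, 40, df = 0, da = 0,
                       fm_depth = 40, fm_rate = 10)
  expect_true(is_rapid_fm(trfm10, 30))
  trfm <- with_event(tr, 20, 40, df = 0, da = 0, fm_depth = 40)
  expect_true(is_rapid_fm(trfm, 30))
  # slow drift of 1 Hz/s: SD over 0.5 s ~ 0.14 Hz
  t <- seq(0, 60, by = 0.05)
  drift <- make_track(t, 850 + t, rep(-30, length(t)))
  expect_false(is_rapid_fm(drift, 30))
  # too few frames
  sparse <- make_track(c(0, 10, 20), rep(850, 3), rep(-30, 3), hop = 10)
  expect_false(is_rapid_fm(sparse, 10))
})

test_that("detection requires all three criteria jointly", {
  base <- flat_track(jitter_f = 3, jitter_a = 0.5)

  full <- detect_events(with_event(base, 30, 32))
  expect_equal(nrow(full), 1L)
  ov <- min(full$offset, 32) - max(full$onset, 30)
  expect_gt(ov / 2, 0.8)                     # >= 80% overlap with truth

  # no FM: criterion 3 gates
  expect_equal(nrow(detect_events(with_event(base, 30, 32, fm_depth = 0))),
               0L)
  # +20 Hz: below the 25 Hz frequency criterion
  expect_equal(nrow(detect_events(
    with_event(base, 30, 32, df = 20, fm_depth = 8))), 0L)
  # +5 dB only: below the 10 dB amplitude criterion
  expect_equal(nrow(detect_events(with_event(base, 30, 32, da = 5))), 0L)
})

test_that("detection is monotone in its thresholds and criteria", {
  base <- flat_track(jitter_f = 3, jitter_a = 0.5)
  tr <- with_event(with_event(base, 20, 22), 40, 41.5, df = 30, da = 11)
  n_def <- nrow(detect_events(tr))
  expect_gte(n_def, 1L)
  # raising thresholds never increases the number of events
  expect_lte(nrow(detect_events(tr, df_min = 45)), n_def)
  expect_lte(nrow(detect_events(tr, da_min = 14)), n_def)
  # dropping criterion 3 enlarges (or preserves) the event set
  expect_gte(nrow(detect_events(tr, fm_sd_min = 0)), n_def)

  ev <- detect_events(tr)
  if (nrow(ev) > 1) expect_true(all(diff(ev$onset) > 0) &&
                                  all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
})

test_that("phase segmentation follows the drop-trim arithmetic", {
  tr <- flat_track()
  ev <- list(onset = 10, offset = 12)       # 2.0 s event, trim 0.2
  seg <- segment_phases(ev, tr, mode = "mixed")
  pts <- seg$phase_points
  early <- pts[pts$phase == "EARLY", ]
  late <- pts[pts$phase == "LATE", ]
  # EARLY spans [10, 10.9], LATE [10.9, 11.8]
  expect_true(all(early$t >= 10 - 0.05 & early$t <= 10.9 + 0.05))
  expect_true(all(late$t >= 10.9 - 0.05 & late$t <= 11.8 + 0.05))
  expect_false(seg$low_resolution)

  # minimal 0.5 s event: phases of 0.225 s, low resolution flagged
  seg2 <- segment_phases(list(onset = 10, offset = 10.5),
                         flat_track(dt = 0.2), mode = "mixed")
  expect_true(seg2$low_resolution)

  # playback mode: BEFORE points in [onset - 1.5, onset)
  seg3 <- segment_phases(ev, tr, mode = "playback")
  before <- seg3$phase_points[seg3$phase_points$phase == "BEFORE", ]
  expect_true(all(before$t >= 10 - 1.5 - 0.05 & before$t < 10 + 0.05))
})

test_that("the first segment of the nearest interaction is selected", {
  ev <- structure(data.frame(
    onset = c(100, 101.5, 200), offset = c(101, 102.5, 202),
    duration = c(1, 1, 2), interaction_id = c(1L, 1L, 2L),
    segment_index = c(1L, 2L, 1L), peak_f0 = 900, peak_amp = -20,
    n_frames = 10L), class = c("interaction_events", "data.frame"))
  # t = 190: interaction at 200 s is nearest
  expect_equal(first_segment_near(ev, 190)$onset, 200)
  # t = 101: inside the multi-segment interaction, first segment returned
  near <- first_segment_near(ev, 101)
  expect_equal(near$segment_index, 1L)
  expect_equal(near$onset, 100)
  # out of radius / no events
  expect_null(first_segment_near(ev, 500))
  expect_null(first_segment_near(ev[0, ], 100))
})
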