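# swarmtone

Flight-tone tracking and harmonic convergence analysis for *Anopheles
gambiae* mating-swarm audio.

Male mosquitoes swarm at dusk and find mates acoustically. Each sex
advertises a wingbeat "flight tone" — a female fundamental (F1) near
550 Hz and a male fundamental (M1) near 850 Hz, each with harmonic
overtones — and during a mating attempt the male tone rises in frequency
and amplitude and acquires rapid frequency modulation. Courting pairs can
*harmonically converge*: a male and a female overtone meet at nearly the
same frequency, classically at the male second and female third harmonics
(M2:F3), which for a 900 Hz male and 600 Hz female coincide exactly at
1,800 Hz. swarmtone is for researchers who want to quantify this behaviour
from swarm recordings (or validate such an analysis end to end without
any recordings at all).

## What it computes

Given a mono WAV of a 1-h swarm sequence, the pipeline:

1. learns a noise profile from the 10 s silent lead-in and applies
   spectral-subtraction denoising (`build_noise_profile`,
   `subtract_noise`);
2. tracks the male (700–1100 Hz) and female (400–700 Hz) fundamentals
   through Hann/zero-padded STFT spectrograms with parabolic sub-bin peak
   interpolation (`compute_spectrogram`, `peak_in_band`,
   `track_recording`);
3. detects mating-interaction tones as maximal runs of frames satisfying
   all three criteria — f0 rise ≥ 25 Hz and amplitude rise ≥ 10 dB over
   the background males, plus rapid frequency modulation
   (`detect_events`);
4. splits each sampled interaction into phases, computes harmonic
   frequency differences at the four ratios M1:F2, M2:F3, M3:F4, M3:F5,
   bins them into the half-open categories `<5` (convergence), `<10`,
   `<20`, `<50`, `>50` Hz, and assigns outcome scenarios
   (`segment_phases`, `best_outcome`, `scenario_mixed`,
   `scenario_playback`);
5. tabulates everything with the matching contingency statistics:
   equal-probability chi-square goodness of fit with BH post-hoc
   comparisons, continuity-corrected 2×2 chi-square, and the two-sided
   Fisher exact test (`build_report`, `chisq_gof`, `chisq_2x2_corrected`,
   `fisher_exact`, `bh_adjust`).

Two generators close the loop:

* `make_schedule` / `render_playback` synthesize the artificial playback
  stimuli (15 min silence, then 45 min of alternating 5 s baseline /
  interaction tone periods — 270 + 270 periods at 550/600 Hz female or
  850/900 Hz male — with five stacked harmonics), and
* `simulate_swarm` produces seeded synthetic swarm audio with a
  ground-truth event log, so detector sensitivity/precision and
  per-period frequency recovery are measurable exactly.

## Worked example

A desk-scale synthetic run — 600 s of a mixed-sex swarm with 12 injected
interaction events at +50 Hz / +15 dB with FM:

```r
library(swarmtone)
cfg <- mixed_config(n_events = 12, interaction_df_hz = 50,
                    interaction_da_db = 15, seed = 42)
sim <- simulate_swarm(cfg, duration_s = 600)
an  <- analyze_swarm(sim)
head(an$events[, c("onset", "offset", "peak_f0", "peak_amp")], 3)
#>      onset   offset  peak_f0  peak_amp
#> 1  2.44125  3.97575 939.8762 -14.13593
#> 2 35.43300 36.64200 919.5484 -13.15381
#> 3 114.87825 116.20350 922.8643 -15.62149
```

All 12 injected events are recovered (onsets within a frame hop of the
ground truth in `sim$truth$events`); `peak_f0` near 920–960 Hz is the
injected +50 Hz step plus ±40 Hz FM on top of the ~843 Hz male chorus,
and `peak_amp` sits ~15 dB above the chorus level. The report assembles
the tabulations:

```r
build_report(an, interactions = sampled_interactions(an, times = c(150, 300, 450)))
#> -- Outcome scenarios (5-min cadence) --
#>       scenario n
#>        S1_BOTH 2
#>  S2_EARLY_ONLY 0
#>   S3_LATE_ONLY 1
#>      NONE_GT50 0
#> GOF chi-square = 3.667, df = 3, p = 0.2998
```

Here two of the three sampled interactions achieved a harmonic
difference below 50 Hz in both the early and late phase (scenario 1) and
one only late (scenario 3); three sampling points are far too few for
the scenario GOF to be significant, as the p-value says.

Harmonic arithmetic directly:

```r
harmonic(900, 2)               # 1800
best_outcome(900, 600)         # ratio M2F3, diff 0, category LT5
fisher_exact(matrix(c(77, 73, 43, 47), 2))   # 0.6892695
chisq_gof(c(51, 26, 22, 21))$statistic       # 20.06667
```

## Package layout

* `R/audio_clip.R`, `R/stft.R`, `R/noise.R` — audio container, WAV I/O,
  STFT spectrograms, peak interpolation, spectral subtraction
* `R/tone_tracking.R` — band tracking, swarm periods, cadence sampling
* `R/interaction.R` — three-criteria event detection, phase segmentation
* `R/harmonics.R` — ratios, difference categories, outcome scenarios
* `R/playback.R` — stimulus schedules, rendering, round-trip checks
* `R/swarm_synth.R` — the seeded synthetic swarm generator
* `R/stats.R`, `R/report.R`, `R/pipeline.R` — statistics, tabulation,
  end-to-end wrapper

The methods vignette (`vignettes/swarm-acoustics.Rmd`) documents the
models, the tunable parameters and the design decisions in detail.
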