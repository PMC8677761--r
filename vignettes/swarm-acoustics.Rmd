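---
title: "Swarm acoustics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm acoustics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmtone)
```

## The measurement problem

Male *Anopheles gambiae* form mating swarms at dusk; females enter the
swarm in brief bouts of "offering flight". Both sexes advertise
themselves acoustically through their wingbeat ("flight") tones: the
female fundamental (F1) sits near 550 Hz, the male fundamental (M1) near
850 Hz, each with a ladder of harmonic overtones (F2–F5, M2–M4). During
a mating attempt the male's tone jumps up in frequency and amplitude and
acquires rapid frequency modulation, and the pair can *harmonically
converge*: a male overtone and a female overtone meet at nearly the same
frequency, classically at M2:F3 near 1,800 Hz (for a 900 Hz male and a
600 Hz female, `2 * 900 = 3 * 600 = 1800` exactly).

swarmtone turns a mono swarm recording into that analysis: per-sex
fundamental tracks, detected mating-interaction tone events, harmonic
frequency-difference outcomes per interaction phase, and the contingency
statistics over outcome tables. Because real swarm recordings of this
kind are not publicly deposited, the package carries a first-class
synthetic swarm generator with ground-truth logs, so every stage is
validated by parameter recovery rather than by eye.

## Spectral measurements

All measurements are made on short-time Fourier spectrograms with a Hann
window. The default geometry is a 4096-sample window at 44.1 kHz
(~92.9 ms — the same physical window length is used at any sample
rate), 75% overlap, and 4x zero-padding, giving a refined bin spacing of
~2.7 Hz. Sub-bin precision comes from 3-point parabolic interpolation of
the peak in the dB domain; on a clean tone the frequency error is well
below half a (refined) bin. This precision budget is what makes a
strict "< 5 Hz" convergence category measurable at all.

Magnitudes are sine-calibrated: a full-scale sine reads 0 dBFS. The
recording chain's absolute SPL calibration is unrecoverable and
irrelevant here — every amplitude criterion in the pipeline is a
*difference* of dB values, from which the reference cancels.

A tone is only reported in a band when its peak is an *interior* local
maximum (a maximum pinned at a band edge is the skirt of a tone centred
outside the band) standing at least 12 dB above the band's median
level. That prominence gate is what distinguishes "no flyer in this
band right now" from a tracked tone. The 12 dB default is set by noise
statistics: across the ~30 independent Rayleigh-distributed bins of a
300 Hz band, the maximum of pure noise exceeds the band median by about
7 dB in expectation, so a 6 dB gate would fire on noise most of the
time, while any real flyer tone sits tens of dB above the in-band noise
median and clears 12 dB trivially. An absolute floor of -80 dBFS
completes the gate: the window-leakage sidelobes of a strong tone
centred *outside* the band form interior local maxima roughly 80 dB
below their source, which would otherwise be "prominent" whenever the
band is near the numerical floor.

Noise reduction is magnitude-domain spectral subtraction. A profile
(per-bin magnitude mean and SD) is learned from the silent lead-in
recorded before mosquitoes enter the cage; each frame magnitude is then
reduced by `over_subtraction * (mean + sd)` (default factor 1) and
floored at 2% of its original value, with phase preserved. The floor
prevents musical-noise holes; reconstruction uses weighted overlap-add
normalised by the accumulated squared window, which is exact for any
hop. This realises the background-noise-subtraction step of the
recording workflow without attempting a bit-for-bit reproduction of any
particular audio editor's algorithm.

## Tracking and the swarm timeline

The female band is (400, 700) Hz and the male band (700, 1100) Hz,
chosen around the reported fundamentals (the female tone sits roughly
300 Hz below the male's); they do not overlap, so no frame can be
claimed by both tracks. Frequency jumps above 150 Hz between consecutive
tracked frames start a new track segment — the continuity gate that
separates distinct flyers.

The 1-h swarm sequence is binned into four 15-min periods — pre-swarm
(dusk), peak, waning and late swarm — as half-open intervals, so
t = 900 s belongs to the peak period. Tracks are sampled every 60 s on
an exact grid, snapping each grid point to the nearest tracked frame
within ±2 s or marking it absent; a full hour therefore yields 60
samples, 15 per period.

## Interaction detection

A mating-interaction tone must satisfy three criteria *jointly*,
relative to the background swarming males: a ≥ 25 Hz frequency rise, a
≥ 10 dB amplitude rise, and rapid frequency modulation. The background
is the rolling median over a ±10 s window, re-estimated near candidate
runs with candidate frames excluded (medians are robust to the 1–2 s
excursions typical of free-flight interactions, but exclusion removes
any residual bias from long events).

"Rapid frequency modulation" is a behaviour, not a number, so the
package quantifies it: the standard deviation of tracked f0 over a
0.5 s window must reach 15 Hz. This is the pivotal free parameter of the
detector. For scale: ±40 Hz sinusoidal FM has a sampled SD of ~28 Hz,
comfortably above the gate, while OU-like baseline jitter with a 15 Hz
stationary SD changes much more slowly and stays far below it over
0.5 s windows.

Qualifying frames are merged across gaps shorter than 0.25 s — FM
periodically swings the instantaneous excursion below threshold for a
fraction of each modulation cycle, and merging reunites those
sub-criterion dips — and runs shorter than 0.5 s are discarded, both
reflecting reported free-flight interaction durations of roughly 1–2 s.
Detected events separated by under 2 s are treated as segments of one
multi-segment interaction, and when an interaction is sampled on the
5-min cadence only the first segment of the temporally closest
interaction (within ±150 s, half the cadence) is analysed.

Each analysed interaction is split into phases. In mixed-sex mode the
event span, minus a drop-out trim of `min(0.2 s, 10%)` at the end
(tones emitted as the couple falls from the swarm are excluded), is
halved into EARLY and LATE. In playback mode the phases are BEFORE (the
1.5 s of background male tone preceding onset) and DURING. Every phase
is sampled at three time points at 10%, 50% and 90% of its span; phases
too short for three distinct frames reuse frames and flag
`low_resolution`.

## Harmonic outcomes

Overtones are estimated from sampled fundamentals (`harmonic(f1, n) =
n * f1`), and differences assayed at four ratios: M1:F2, M2:F3, M3:F4,
M3:F5. Categories are half-open — `[0,5)` convergence, `[5,10)`,
`[10,20)`, `[20,50)`, `[50,Inf)` — so exactly 5 Hz is *not* convergence
and exactly 50 Hz falls in the > 50 Hz class; a consequence worth
knowing is that the nominal baseline pair 850/550 Hz differs by exactly
50 Hz at M2:F3 and lands just outside the achieved classes.

Two collapsing rules are deliberate design choices the source design
leaves open. First, a phase's category is the category of the *minimum*
difference across its three sample points (an interaction phase
"achieves" a difference if it does so at any sampled moment). Second, in
mixed-sex scoring each phase may be satisfied by any ratio
independently; requiring the same ratio early and late would be
stricter, but nothing in the design motivates coupling the phases.

Mixed-sex interactions then fall into scenario 1 (achieved early and
late), 2 (early only), 3 (late only) or the separate > 50 Hz outcome;
sampling points with no interaction present also count as > 50 Hz.
Playback interactions are scored against four references — the baseline
and interaction playback tones, each before and during the event —
giving a 4-bit achievement lattice of 16 cells; the observed scenarios
of such an experiment are a subset of this lattice, and the package
reports cells ordered by empirical frequency rather than guessing
labels for unobserved ones.

## Playback stimuli

`make_schedule()` encodes the canonical 1-h stimulus: 15 min of silence,
then 45 min of alternating 5 s periods — 270 baseline and 270
interaction periods — at 550/600 Hz (female) or 850/900 Hz (male).
`render_playback()` stacks five sine harmonics with a default `1/k`
amplitude rolloff (the stack is fully configurable), applies 10 ms
raised-cosine ramps at period boundaries to avoid clicks (phase is
continuous within a period and resets at boundaries), and normalises to
-3 dBFS. Alternation starts with the baseline tone; the design counts
are unaffected by that choice. The sampling plan follows the design
arithmetic: 105 tone samples per trial (15 in silence + 90 in
alternation), 315 over three trials; 540 period-presence assays per
trial, 1620 over three.

## The synthetic swarm generator

The generator's defaults *are* the study conditions, not tuning knobs: a
30:10 male:female swarm (single-sex presets use 40), male base 843 Hz
and female base 550 Hz, per-period participation fractions
(0.14/0.58/0.43/0.31) and a peak-period frequency elevation such that
PEAK sits 30 Hz above PRE, interaction events at +50–60 Hz and
+10–24 dB with ±40 Hz sinusoidal FM, Gaussian background noise at
-50 dBFS RMS, and a 10 s noise-only lead-in.

Individual wingbeat trajectories are mean-reverting
(Ornstein–Uhlenbeck) walks with 15 Hz stationary SD and a 2 s reversion
time — the simplest process producing realistic, continuously wandering
spectrogram ridges. Females fly in intermittent 3–10 s bouts. Events
use 50 ms raised-cosine onsets so criteria margins are controlled, are
scheduled with a 3 s global separation (re-drawn, never emitted
overlapping), and are assigned to males active in their period.

Two numerical choices deserve emphasis:

* **Event amplitude semantics.** The injected amplitude excursion
  `interaction_da_db` is defined *relative to the background male chorus
  level*, exactly as the detection criterion is. Since the measured
  chorus is an energy sum of the period's active males, the generator
  boosts the interacting male by `da + 10 log10(n_active)`. Defining the
  step relative to the individual's own baseline instead would make the
  injected and measured excursions incommensurate (chorus overlap and
  FM smearing together absorb 5–8 dB), i.e. the ground-truth log would
  not mean what the detector measures.
* **Sample rate.** The simulator synthesises at 8 kHz, the minimum
  standard rate that keeps the highest modeled overtone (the male
  fourth harmonic during interactions, ≈3.8 kHz) below Nyquist. The
  playback renderer defaults to 44.1 kHz; arbitrary rates ≥ 8 kHz are
  accepted on input everywhere.

What the simulator does *not* emulate: spatial acoustics and
microphone directivity, Doppler shifts, amplitude dynamics of couples
dropping out of the swarm (the drop-trim is exercised with synthetic
decays only), and any auditory-system nonlinearity. Passing
parameter-recovery tests therefore demonstrates that the pipeline
measures what the generator injects under realistic spectral-temporal
structure and noise — not that it is robust to every artefact of real
cage recordings.

## Statistics

Scenario count tables are tested by an equal-probability chi-square
goodness of fit with BH-adjusted pairwise post-hoc comparisons;
presence/absence by playback period uses the continuity-corrected 2x2
chi-square; phase proportions use the two-sided Fisher exact test under
the minimum-likelihood rule. These are validated wrappers over the base
R implementations — the package's contribution is the acoustics, not
the contingency statistics. One property worth noting: the BH step-up is
*not* idempotent (re-adjusting adjusted values multiplies sorted values
by `m/i` again), so the test suite checks it against the closed-form
step-up oracle instead.

## Worked example

A desk-scale run (sizes chosen to keep the example fast; the full study
conditions are a 3600 s swarm):

```{r, eval = FALSE}
cfg <- mixed_config(n_events = 12, interaction_df_hz = 50,
                    interaction_da_db = 15, seed = 42)
sim <- simulate_swarm(cfg, duration_s = 600)
an <- analyze_swarm(sim)
an$events[, c("onset", "offset", "peak_f0", "peak_amp")]
build_report(an, interactions = sampled_interactions(an, times = c(150, 300, 450)))
```

## Known limitations

* Tracking reports one tone per band per frame — the dominant flyer.
  Overlapping same-band tones (two simultaneous interactions) are
  resolved in favour of the louder one.
* The 12-scenario playback taxonomy is realised as the full 16-cell
  lattice; cell labels beyond the achievement signature are empirical.
* Absolute amplitude calibration is deliberately out of scope; only dB
  differences are meaningful.
* Period-level statistics treat 60 s samples as exchangeable within a
  period; repeated-measures structure across trials is delegated to
  standard model fits (`aov`, `TukeyHSD`) on the exported tables.
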