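---
title: "Methods: song and peri-song neural activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: song and peri-song neural activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`perisong` implements a pipeline for asking when songbird premotor neurons
are active relative to singing: during the song itself, or in the seconds
of preparation and recovery that surround it. This vignette documents the
models and procedures, the tunable parameters, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## Behavioral timeline

All analyses hang off a temporal scaffold built from syllable annotations
(`onset_s`, `offset_s`, `label`). Labels fall into introductory notes
(`intro`), motif syllables (any other non-reserved label), `call`, and
`noise`. Introductory notes and motif syllables are *song elements*; calls
are vocal but not song.

- **Phrases.** Song elements separated by silent gaps strictly shorter than
  2 s belong to one song phrase; a gap of 2 s or more starts a new phrase
  (the inequality is strict: a 2.0-s gap splits). Phrase onset is the onset
  of the first vocal element, introductory notes included.
- **Bouts.** Within a phrase, elements separated by less than `bout_gap`
  (default 0.5 s) form one bout. The threshold is our choice: intra-bout
  syllable gaps (mini-breaths) are tens of milliseconds while inter-bout
  silences run roughly 0.8–1.8 s, so any value in between partitions
  identically; 0.5 s sits safely inside that dead zone.
- **Epoch mask.** Every sample of a time grid receives exactly one label:
  `song` (inside a bout), `peri_gap` (silent gaps between bouts of one
  phrase), `peri_pre`/`peri_post` (up to 5 s before/after a phrase),
  `baseline` (at least 10 s from any song bout or call), `other`. All
  intervals are half-open `[onset, offset)` and frames are labeled by their
  start time, which prevents double counting at boundaries. When the post
  window of one phrase would overlap the pre window of the next, the
  midpoint of the inter-phrase gap splits them — a symmetric, deterministic
  rule; song always takes precedence over peri labels. Calls inside peri
  windows keep the peri label (they are vocal but not song) and reset the
  baseline exclusion clock. The three peri labels are merged into a single
  "peri-song" category wherever events are counted; exposing `peri_gap`
  separately costs nothing and lets gap activity be inspected on its own.
- **Eligibility.** A phrase enters pre-song analyses only if no vocal
  element occurs within 5 s before its onset (post-song: within 5 s after
  its offset); phrases truncated by the trial edge are flagged ineligible.

## Calcium pipeline

Per-neuron fluorescence is the ROI pixel mean minus the mean of a ring
extending 6 pixels around the ROI (excluding all neuronal ROI pixels), with
unit weight — plain subtraction, no neuropil coefficient.

**Baseline, noise, activity.** The noise SD is estimated once, robustly, as
`1.4826 * mad(diff(y)) / sqrt(2)`. The first-difference route matters: the
indicator decay constant (~1.25 s) is long relative to typical inter-event
intervals during song, so fluorescence can stay elevated through an entire
phrase and any estimator based on the spread of "quiescent" samples
inflates badly in exactly the regime of interest; frame-to-frame
differences are noise-dominated except at sparse, fast onsets, which the
median absolute deviation ignores. The baseline is then iterated to a
fixed point of: (1) running 20th-percentile filter (30-s window, evaluated
on a 0.5-s grid and interpolated) over currently quiescent frames, offset
by `qnorm(0.8) * sigma` so the percentile is an unbiased location estimate
under Gaussian noise; (2) active frames = residual above `3 * sigma`,
dilated 2 frames backward and 0.75 s forward. The forward dilation covers
decay tails that sit below threshold but well above baseline; without it
the percentile dips just after activity and creates spurious rebound
events. A floor of `1e-6 * max(|y|, 1)` keeps the SD positive on noiseless
input. Iteration stops when the active mask repeats (at most 20 passes).

**Deconvolution.** The baseline-subtracted trace is deconvolved under an
AR(1) calcium model by solving

$$\min_c \sum_t (y_t - c_t)^2 \quad \text{s.t.}\quad c_t \ge \gamma\,
c_{t-1},\; c_t \ge 0,$$

with a single backward-merging pool-adjacent-violators pass (pools of
adjacent samples with geometrically decaying fit; a pool whose truncated
height violates the decay constraint against its predecessor is merged,
and merging propagates backwards). The per-frame drive is
$s_t = c_t - \gamma c_{t-1} \ge 0$. The default
$\gamma = \exp(-\Delta t / 1.25\,\mathrm{s})$ comes from the GCaMP6s decay
time; the indicator is named by the experiments, its time constant is not,
and 1.25 s is a standard literature value — it is configurable. The test
suite checks the solver against an independent box-constrained quadratic
program on the innovation parameterization.

**Event detection.** An event is a maximal run of frames where the
deconvolved trace exceeds `3 * sigma`; runs separated by fewer than 2
sub-threshold frames are merged. Onsets come from the drive: the first
positive-drive burst in a run marks the first event, and any later burst
whose peak drive exceeds `3 * sigma` splits off another event (this is
what resolves two transients half a second apart riding on one another's
decay). Because a positive increment at frame $i$ means calcium rose
during frame $i-1$'s interval, the onset is placed one frame before the
burst start; peaks take the earliest frame on ties. Rise time is peak
minus onset. The 3-SD rule is applied to the deconvolved trace (a flag in
`detect_events` is unnecessary since the raw-variant can be obtained by
deconvolving with `gamma` near 0); applying it to the deconvolved trace
matches how the thresholds are drawn against inferred traces in this
analysis tradition.

## Population analysis

- **Phrase index.** $(n_{song} - n_{peri}) / (n_{song} + n_{peri})$,
  bounded to $-1$ (peri-song exclusive) and $+1$ (song exclusive). Neurons
  with fewer than two song+peri events in a day are excluded — sparse
  sampling would otherwise spuriously mark neurons class-exclusive. Events
  labeled baseline/other stay out of the denominator; with both bounds
  attainable only this reading of "total events" is consistent. Counts
  pool across trials within a day; across days, neurons are distinct
  identities.
- **Classes.** Index $-1$: peri-song neuron; $+1$: song neuron; interior:
  pan-song. A helper selects pan-song neurons within $\pm 0.18$ of zero
  for amplitude comparisons.
- **Rate traces.** Event onsets are binned at 100 ms over $\pm 5$ s around
  phrase onset/offset, converted to events/s, averaged across (eligible)
  phrases — per-phrase averaging is the default, a pooled mode exists —
  and smoothed with a centered 1-s moving average that never crosses the
  $\pm 5$ s edges or the alignment point and never shrinks below 0.5 s
  (near a boundary the window is clipped and re-extended away from the
  boundary to keep at least 0.5 s). Unsmoothed traces integrate exactly to
  event counts.
- **Onset prediction.** Baseline mean and SD of the smoothed population
  rate come from $[-5, -4]$ s; the predicted crossing is the earliest
  subsequent pre-onset time where the rate exceeds mean + 3 SD and stays
  there for 0.2 s. The dwell requirement (our choice) suppresses
  single-bin noise crossings; an SD floor of 0.05 events/s handles silent
  baselines.
- **Histograms, SNR, interval fluorescence, active fractions.** 200-ms
  peri-event histograms count either events or distinct active neurons per
  bin. SNR is peak fluorescence of each song event over the neuron's mean
  fluorescence in a quiet 5-s baseline window, averaged per neuron.
  Interval fluorescence divides the mean background-subtracted
  fluorescence in baseline/pre/post windows by the song mean. Active
  fractions are per-phrase percentages of neurons with at least one event
  in that phrase's song (or peri) epoch, summarized as mean ± SD across
  phrases.

## Electrophysiology

Multiunit voltage is band-passed 0.3–5 kHz with a 4th-order Butterworth
run forward–backward (zero phase; only the band is prescribed, the filter
family is ours). Spikes are negative local minima below 4 SD of the
filtered signal over spontaneous segments (more than 10 s from song), with
a 1-ms lockout keeping the most negative peak. Aligned rates use 10-ms
bins averaged across renditions and a 500-ms centered moving average;
normalization maps the baseline mean to 0 and the song mean to 1. Onset
latency is the earliest pre-song time at which the smoothed rate crosses
mean + 2 SD of the spontaneous rate and stays above it until song onset
(offset symmetric). The spontaneous statistics are computed on the
smoothed trace over spontaneous segments; because the threshold is applied
to a trace averaged over $n$ renditions, the spontaneous SD is divided by
$\sqrt{n}$ so both sides live on the same averaging scale — without this
the threshold is systematically conservative and latencies bias late.

Single-unit analysis samples four epochs per bout: spontaneous (>10 s from
bouts), pre-song ($-2.5$ to $-0.5$ s before the first vocal element), song,
post-song ($+0.5$ to $+2.5$ s). ISIs must have both spikes inside one
window (boundary-spanning ISIs are discarded, not truncated); the CV is
the sample SD over the mean of within-epoch ISIs pooled per unit, with
epochs under 5 ISIs flagged insufficient. Sample (n−1) SDs are used
throughout.

## Respiration

Pressure traces are low-passed at 400 Hz; ambient is the median over a
quiet window (default the first 3 s). Phase transitions use a hysteresis
band of ±5% of the quiet-breathing peak-to-peak: the state becomes
inspiratory only below ambient − band and expiratory only above ambient +
band, and the band-crossing samples mark the onsets. A cycle runs from one
inspiration onset to the next, so durations are differences of
consecutive onsets and the (small, symmetric) band-crossing delay cancels;
cycles without an expiratory phase and partial edge cycles are dropped.
The hysteresis band is also this package's resolution of the "return to
ambient" ambiguity for asymptotically decaying expirations. Duty cycle is
the percentage of the cycle spent in the expiratory phase, and by
construction duty + inspiratory fraction = 100 exactly. Song onset is the
inspiration preceding the first introductory note; song offset the end of
the expiration generating the last syllable. Cycles are assigned to
pre/song/post by inspiration onset, summarized per song, per bird and in
1-s bins; songs lacking 3 s of uninterrupted quiet respiration on either
side are excluded, and exclusion of songs preceded by calls or movement is
honored via annotation flags, not inferred from the signal.

## Synthetic-data generator

The generator's defaults define the study conditions the tests run under:

| parameter | default | basis |
|---|---|---|
| frame rate | 30 frames/s | imaging rate |
| phrases per day | 2 (timeline), 6 for classification runs | a day of directed singing pools multiple trials |
| bout/phrase gaps | 0.8–1.8 s / 12–16 s | straddle the 2-s rule from both sides |
| motif length | ~0.63 s (4 syllables) | stereotyped motif in the 0.6–1 s range |
| kernel rise / decay | 0.029 s / 1.25 s | puts the kernel peak at 0.112 s |
| song-event jitter | 55 ms SD, truncated ±2.5 SD | reported onset precision |
| per-motif participation | 0.7 | reported participation probability |
| peri ramp peak | −1.5 s, 0.8 events/s | reported peak of peri-song event rate; ~3 events/phrase/neuron |
| event amplitude | N(8, 1.5²) floored at 5 (noise-SD units) | well-separated transients, as in the imaging data |
| MU rates | 25 → 70 Hz, ramp from −1.5 s | reported pre-song multiunit onset |
| SU gamma shapes | 8 spontaneous / 0.5 in song epochs | tonic → irregular transition |
| respiratory cycles | N(0.38, 0.04²) quiet / N(0.18, 0.03²) song, duty 58/57% | reported cycle statistics |

Quiet respiratory cycles include an end-expiratory pause at ambient
(one quarter of the expiratory phase): real breathing dwells at ambient
between breaths, and that dwell is what makes the quiet-window median a
consistent ambient estimator. Event schedules use one substream per
neuron derived from the master seed, so growing the population never
perturbs existing neurons' data. Identical (config, seed) reproduce
identical outputs bit for bit.

The generator emulates the statistical structure the analyses assume —
class-structured event schedules, kernel-shaped transients with Gaussian
noise and slow sinusoidal drift, rate-modulated point processes,
state-switched respiratory cycles. It does not emulate motion artifacts,
photobleaching, neuropil cross-contamination beyond a flat background,
spike-waveform variability, or acoustic structure. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
regime, not robustness to every artifact of real recordings.

## Problem sizes and numerical choices

Test and analysis runs use populations of up to 120 neurons over ~2-minute
timelines with six phrases, 20-rendition multiunit channels, 19 single
units and 20-seed respiratory sweeps — sizes chosen to give stable
statistics (binomial/Poisson counting error a few percent) while keeping
each suite comfortably interactive. Degenerate inputs are handled
explicitly: empty vocal tables give empty phrase lists; constant traces
get a noise floor rather than a zero SD; all-zero deconvolved traces
normalize to zero; traces with every frame active, channels without
spontaneous segments, masks without song frames, and pressure traces where
no cycle precedes the first note all raise informative errors. Ties in
peak location take the earliest frame; event runs separated by a single
sub-threshold frame are merged.

## Known limitations

- The onset-frame convention quantizes event onsets to the imaging frame
  grid; sub-frame timing is not estimated.
- Classification at the phrase-index extremes is brittle by construction:
  a single false event moves a neuron off ±1. The <2-event exclusion
  absorbs the sparse end, but neurons with exactly one detection miss in
  a single class remain the dominant error mode (a few percent at default
  noise).
- The respiration segmenter assumes a calibrated (near-constant-offset)
  pressure signal; slow sensor drift beyond the low-pass band would
  require detrending upstream.
- The multiunit latency estimator presumes the spontaneous segments are
  representative of the baseline firing regime; state changes unrelated
  to song (movement) would widen the threshold.
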