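---
title: "Detecting spontaneous step-like activity and evoked potentials in chronic hind-limb EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spontaneous step-like activity and evoked potentials in chronic hind-limb EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tokeda)
```

## The problem

After a complete mid-thoracic spinal cord injury, rats receiving epidural
stimulation and serotonergic/glycinergic pharmacology can regain spontaneous
hind-limb activity in their home cages. Quantifying that activity over long
unattended sessions requires detecting *step-like events* from nothing but
chronically implanted EMG electrodes in the tibialis anterior (TA, ankle
flexor) and soleus (Sol, ankle extensor) of each hind limb, and relating the
behaviour to spinally evoked potentials (MEPs) recorded on the same
electrodes during sub-threshold 40 Hz stimulation. `tokeda` implements the
complete offline analysis chain plus a ground-truth synthetic generator, so
every stage is testable without animal recordings.

## The envelope: band-pass, energy operator, smoothing

Raw EMG (mV, 10 kHz) is conditioned in three steps (`condition()`):

1. **Band-pass** 30--1000 Hz, third-order Butterworth, applied
   forward-backward (`signal::filtfilt`). Zero-phase filtering is used
   throughout because the step-timing logic depends on undistorted event
   timing; the cost (acausality) is irrelevant offline.
2. **Teager--Kaiser energy operator**
   $\psi[n] = x[n]^2 - x[n-1]\,x[n+1]$, an instantaneous-energy estimate
   that weights amplitude *and* frequency ($\psi = A^2\sin^2\Omega$ for a
   sinusoid) and therefore sharpens burst onsets relative to plain
   rectification. Endpoints copy the nearest interior value, keeping input
   and output lengths equal; the operator is quadratic, so the whole chain
   scales as $k^2$ when the input scales by $k$.
3. **Rectify + low-pass** at 50 Hz (Butterworth; order 3, matching the
   band-pass order -- the smoother's order is a free choice and is exposed
   in the configuration). Negative post-filter ripple is clipped so the
   envelope is non-negative.

The envelope is in mV^2-scale energy units. We smooth the energy trace
itself (not its square root): the detector only ever compares the envelope
against thresholds derived from the same trace, so the monotone square is
immaterial to detection and we follow the literal order of operations of
the conditioning chain.

## Adaptive double thresholding

Recordings are processed in 10-minute segments, each cut into 10 s bins.
Within each bin (`find_rest_period()`):

* the envelope is block-averaged over 10 ms windows;
* the minimum-mean block seeds the rest window (earliest block on ties, for
  determinism);
* the window grows left and right while two criteria hold:
  * **first-differential stop** -- by default the block-to-block change may
    not exceed `dmax_rel = 500` multiples of the seed rest level per
    second. A genuine burst onset multiplies the envelope several-fold
    within a block or two (thousands of %/s in these units) while
    rest-level modulation -- noise, and the 40 Hz stimulation-locked ripple
    present whenever stimulation is on -- stays one order of magnitude
    lower. Expressing the stop relative to the seed makes rest discovery,
    and with it every downstream threshold and detection, exactly
    invariant under positive rescaling of the raw channels; that matters
    because the absolute gain of a chronic implant drifts over weeks. An
    absolute mode (`dmax_mode = "absolute"`, `dmax` in envelope units/s)
    is available for calibrated data.
  * **log-deviation stop** -- the running sum of
    $|\ln(m_b / m_\mathrm{seed})|$ over admitted blocks may not exceed
    `log_thresh = 300`. Slow ramps never trip a per-block differential;
    their *cumulative* log-deviation from the rest seed does. The exact
    functional form of a "logarithmic threshold" is a design choice of
    this package: the criterion is zero on flat signals, accumulates on
    ramps, is dimensionless (hence scale-invariant), and can be disabled
    (`use_log = FALSE`).
* rest mean and standard deviation ($\mu_\mathrm{rest}$,
  $\sigma_\mathrm{rest}$) are computed from the raw envelope samples inside
  the grown window (not the block means -- block averaging would bias
  $\sigma$ low).

The burst magnitude threshold is
$\mu_\mathrm{rest} + J\,\sigma_\mathrm{rest}$ with $J = 7$, paired with a
per-muscle **duration criterion**: supra-threshold runs shorter than 0.1 s
(TA) or 0.3 s (Sol) are discarded (`detect_bursts()`). Runs crossing a bin
boundary are judged against each bin's own magnitude threshold but survive
as one burst if the union run meets the duration criterion -- splitting one
physiological burst into two sub-criterion fragments at an arbitrary bin
edge would be indefensible. A trailing bin shorter than 2 s inherits the
previous bin's statistics rather than estimating from too few blocks.

## Step registration from flexor--extensor coordination

Each side is processed independently (bilateral symmetry is a *finding*
about recovery, not a constraint to build in). Both envelopes are
normalized by their own maximum over the 10-minute segment -- the segment is
the natural processing unit, bounds memory, and the normalization absorbs
the missing force calibration -- and subtracted:
$d = \mathrm{TA_{norm}} - \mathrm{Sol_{norm}} \in [-1, 1]$. Positive $d$
means net ankle flexion (swing), negative net extension (stance).

`detect_steps()` registers an event when all gates pass:

| gate | default | meaning |
|---|---|---|
| peak sign/size | $> 0.01$ | local maximum of $d$, strictly positive |
| flexor gating | -- | peak lies inside an active TA burst |
| peak separation | 0.2 s | spacing between accepted candidate maxima |
| last-maximum rule | -- | only the last surviving candidate per TA burst |
| follow window | 0.5 s | $d$ must turn strictly negative within 0.5 s |
| extensor gating | 0.25 s | that negative phase overlaps a Sol burst of at least 0.25 s |

Zero samples are neither flexion nor extension: "negative" is strict.
The 0.2 s separation is applied at the *candidate* level, before the
last-in-burst selection, so a cluster of maxima near the burst end
collapses onto its first member rather than silently passing every member.
Successive negative runs inside the follow window are examined in order and
the event registers on the first run overlapping a qualifying extensor
burst: the extensor envelope crosses its threshold a few tens of
milliseconds after the flexor burst ends, so requiring the *first* dip to
overlap would discard genuine steps on the strength of a noise-level
wobble. One-sample overlap between the negative phase and the Sol burst
suffices by default; stricter containment is a configuration option.

The full cycle window (`step_cycle_window()`) runs from the last
non-positive sample of $d$ before the peak (swing start; clamped to the
segment start with a warning when $d$ is positive from the outset) to the
earlier of $d$'s return to zero and the end of the overlapping extensor
burst (stance end). Flexor bursts that never register a step are counted
separately as non-step activity; they are reported, not classified.

`activity_metrics()` aggregates steps/min per minute bin, per-event stance
periods (stance end minus the flexion-to-extension crossing), cumulative
trapezoidal IEMG normalized 0--1 over the recording, and percent change in
step count against a baseline count (100% = no change; undefined when the
baseline is zero).

## Evoked-potential features

MEP epochs are cut from the *band-passed* trace (not the energy envelope):
25 ms following the end of each stimulation pulse, which at 40 Hz tiles the
record exactly (250 samples at 10 kHz). When step events are supplied, only
epochs lying fully inside a detected swing-to-stance window are kept.
Response windows relative to the epoch start: early 1--4 ms, middle
4--7 ms, late 7--25 ms (half-open); deflections before 1 ms are treated as
stimulation artifact and never counted. The middle and late responses are
commonly read as mono- and polysynaptic pathway markers.

`detect_mep_extrema()` interpolates each epoch to double the point count
(piecewise cubic by default; linear available) and keeps local
maxima/minima passing three filters: topographic prominence at least
0.2 mV, same-type separation at least 0.6 ms (the larger extremum wins),
and second-differential magnitude at least $1.5\times 10^6$ mV/s^2 on the
interpolated grid. The curvature constant is sampling-dependent, so the
configuration stores the rate it assumes (10 kHz) and rescales it by
$(\mathrm{rate}/\mathrm{rate_{assumed}})^2$ with a warning at other rates.
Prominence is in mV on the band-passed trace. On biphasic waveforms the
retained peaks and troughs alternate in time; alternation is *not* enforced
as a filter, because two same-sign lobes separated by a quiet baseline
legitimately produce consecutive peaks with no prominent trough between
them.

Features per epoch (`mep_features()`): trapezoidal IEMG of the rectified
trace over the middle and late windows (the two windows share the 7 ms
boundary sample, so their integrals add exactly to the joint 4--25 ms
integral), peak-to-peak amplitude over the whole epoch, and per-window peak
counts (troughs are reported separately, not folded into "peaks").
`mep_response_summary()` expresses treatment late/middle peak totals as
ratios to a baseline.

## Validation

`match_events()` performs greedy chronological matching: a detection pairs
with the earliest unmatched annotated step whose interval overlaps the
detected swing-to-stance interval or whose onset is within 0.5 s (the
detector's follow window -- annotation onsets are fuzzy at burst
granularity) of the detected flexion-to-extension crossing. Each annotation
matches at most once. Annotated non-functional events count as true
negatives only when no detection overlaps them. `score_events()` computes
accuracy $(tp+tn)/N$, precision $tp/(tp+fp)$ and recall $tp/(tp+fn)$;
undefined ratios are reported as missing, never silently as 0 or 1. The
accuracy denominator is the number of sampled *events* (steps plus
non-functional), the reading most consistent with a mixed event-level
reference set.

## What the synthetic generator emulates -- and what it does not

`simulate_recording()` produces four channels of Gaussian baseline noise
with amplitude-modulated 30--400 Hz noise bursts: TA during each 0.5 s
swing, Sol during each 2 s stance (stance per the reported ~2 s average;
swing and the 0.25 s inter-step gap are plausible values for bipedal rat
stepping, chosen once), scheduled in bouts whose start times follow an
exponentially decaying intensity (half-life 7200 s, emulating the reported
concentration of activity in the first two hours, which is qualitative in
origin). Defaults: burst RMS 0.5 mV against 0.05 mV rest noise (SNR 10),
36 bouts of 6 steps in a 900 s session (216 ground-truth steps -- two
10-minute processing segments, so segmentation is exercised), 40 Hz / 0.2 ms
stimulation artifacts on every channel plus a scaled evoked template after
every pulse (0.1 mV inside step windows, 20% of that outside --
sub-threshold stimulation evokes responses well below burst amplitude, and
because 40 Hz stimulation sits inside the 50 Hz smoother's passband,
burst-scale evoked energy would modulate the envelope at full depth and no
envelope-based burst detector could be expected to cope), and a few
standing-like non-functional events: tonic Sol activity with 20% flexor
co-activation, the extensor-dominant posture of a spinalized rat standing.

EMG texture is modelled at the envelope level only -- amplitude-modulated
band-limited Gaussian noise, the standard surrogate -- with no motor-unit
structure, no electrode artifacts, no movement artifact, no inter-channel
crosstalk, and deterministic swing/stance durations. Passing the end-to-end
tests therefore demonstrates that the detector recovers events whose
envelope statistics match its assumptions at SNR 10; it does not certify
performance on real recordings, where burst shape, co-contraction and
artifact structure are richer (the original validation against video
annotation is not reproducible without the animal data).

`simulate_mep_train()` builds epochs from Gaussian lobes with analytically
known extremum times, amplitudes, prominences ($|a|$) and curvatures
($|a|/s^2$), so the extrema detector can be checked exactly at zero noise
and within one peak per window at SNR 10. Epoch noise occupies the
30--1000 Hz recording band: real epochs are cut from band-passed data, so
wider-band noise could never reach them.

## Numerical choices and degenerate inputs

* Half-open time intervals `[onset, offset)` everywhere; sample `i`
  (1-based) covers `[(i-1)/rate, i/rate)`. A pulse or burst ending at
  sample `i` therefore ends at `i/rate`.
* Rest-window ties seed at the earliest minimum block; growth alternates
  left/right and a side that fails once stays closed -- fully deterministic.
* All-zero channels normalize to all-zero (no 0/0); a flat envelope yields
  $\sigma_\mathrm{rest} = 0$ and a threshold equal to its mean.
* Epochs running past the recording edge are dropped; a recording too slow
  to give 25 samples per epoch is an error, not a silent truncation.
* Simulation sizes in the tests (up to 900 s at 10 kHz, four channels)
  keep the complete suite comfortably within a desktop-scale run while
  exceeding 200 ground-truth events for the recovery checks.

## Known limitations

* No notch filtering or stimulation-artifact blanking inside the envelope
  path; the adaptive threshold absorbs stimulation-locked ripple instead.
* No online/streaming mode; thresholds are not carried across days.
* Kinematic measures (step height, length, speed) are out of reach of
  EMG-only sensing by construction.
* The rest-search growth constants (`dmax_rel`, `log_thresh`) are
  envelope-statistics heuristics; for recordings with very different duty
  cycles they may need adjustment through the configuration.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(duration_s = 120, n_step_bouts = 5, steps_per_bout = 5,
                  seed = 42)
sim <- simulate_recording(cfg)
res <- run_step_detection(sim$recording)
m <- match_events(res$steps, sim$truth, tolerance_s = 0.5)
score_events(m)

feats <- run_mep_extraction(sim$recording, sim$pulses, res$steps)
head(feats)
```
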