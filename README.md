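# tokeda

Offline detection of spontaneous hind-limb **step-like activity** and
extraction of **motor-evoked-potential (MEP) features** from chronic
tibialis anterior (TA, ankle flexor) and soleus (Sol, ankle extensor) EMG,
as recorded from freely moving spinal rats under sub-threshold 40 Hz
epidural stimulation.

After a complete mid-thoracic spinal cord injury, electrical and
pharmacological neuromodulation can re-enable spontaneous cage activity.
Quantifying that activity over six-hour unattended sessions requires a
detector that works from EMG alone. `tokeda` implements the full chain:

1. **Conditioning** — raw EMG (mV, 10 kHz) is band-passed (30–1000 Hz,
   third-order Butterworth, zero-phase), passed through the Teager–Kaiser
   energy operator ψ[n] = x[n]² − x[n−1]·x[n+1], rectified and smoothed
   with a 50 Hz low-pass into a non-negative activity envelope.
2. **Adaptive double thresholding** — per 10 s bin, a rest period is found
   by seeding at the minimum 10 ms block mean and growing while
   first-differential and cumulative log-deviation criteria hold; bursts
   must exceed the magnitude threshold μ_rest + J·σ_rest (J = 7) *and* a
   per-muscle duration criterion (TA 0.1 s, Sol 0.3 s).
3. **Step registration** — the relative-difference signal
   d = TA_norm − Sol_norm (each envelope normalized by its own maximum per
   10-minute segment) represents ankle flexor–extensor coordination. A step
   is registered when a positive peak of d (> 0.01, inside an active TA
   burst, last qualifying maximum in the burst with 0.2 s separation) is
   followed within 0.5 s by a negative phase overlapping a Sol burst of at
   least 0.25 s. Each event carries its full swing-to-stance cycle window.
4. **MEP analysis** — 25 ms stimulation-locked epochs cut from the
   band-passed trace at each 40 Hz pulse end, restricted to detected step
   cycles; early/middle/late response windows at 1–4/4–7/7–25 ms;
   peak/trough detection on a 2× interpolated trace with prominence
   (≥ 0.2 mV), separation (≥ 0.6 ms) and curvature (≥ 1.5×10⁶ mV/s²)
   filters; per-epoch IEMG, peak-to-peak and per-window peak counts.
5. **Validation** — event-level matching against an annotation log with
   accuracy (tp+tn)/N, precision tp/(tp+fp) and recall tp/(tp+fn).
6. **Synthetic data** — a seed-deterministic generator producing
   multi-channel EMG with known ground truth (step schedule, stimulation
   pulses, evoked templates with analytically known extrema), so every
   stage is testable without animal recordings.

See `vignettes/tokeda-methods.Rmd` for the model, parameter rationale and
limitations.

## Worked example

```r
library(tokeda)

cfg <- sim_config(duration_s = 120, n_step_bouts = 5, steps_per_bout = 5,
                  seed = 42)
sim <- simulate_recording(cfg)          # 4-channel EMG + ground truth
res <- run_step_detection(sim$recording)
res
#> <tokeda_result> 120.0 s processed: 23 step event(s), 62 burst(s)
#>   non-step flexor bursts: 5

head(res$steps, 3)
#>   side swing_start_s peak_time_s zero_cross_s stance_end_s
#> 1    L        16.638      17.113       17.178       18.173
#> 2    L        19.431      19.895       19.937       21.910
#> 3    L        22.181      22.448       22.680       24.654

m <- match_events(res$steps, sim$truth, tolerance_s = 0.5)
unlist(score_events(m))
#>  accuracy precision    recall
#>         1         1         1

feats <- run_mep_extraction(sim$recording, sim$pulses, res$steps)
nrow(feats)        # 906 stimulation-locked epochs inside step cycles
colMeans(feats[, c("iemg_mr", "iemg_lr", "peak_to_peak")])
#>      iemg_mr      iemg_lr peak_to_peak
#>        0.916        5.587        1.703
```

Every one of the generator's 23 scheduled steps is recovered with no false
positives; the five standing-like (tonic extensor) events are correctly
left unregistered. Detected swing/stance windows bracket the scheduled
2 s stance phases, and the per-epoch MEP features (IEMG in mV·ms over the
middle/late response windows, peak-to-peak in mV) are computed for every
25 ms epoch inside a detected step cycle.

A command-line wrapper with `condition`, `detect-steps`, `extract-meps`,
`validate` and `simulate` subcommands is installed at
`system.file("cli", "tokeda", package = "tokeda")`.

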