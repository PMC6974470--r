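Package: tokeda
Title: Detection of Step-Like Activity and Evoked Potentials in Chronic Hind-Limb EMG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Offline detection of spontaneous hind-limb step-like activity from
    chronically implanted tibialis anterior (flexor) and soleus (extensor) EMG,
    and extraction of motor-evoked-potential (MEP) features from sub-threshold
    40 Hz epidural-stimulation recordings. Raw EMG is conditioned with a
    Butterworth band-pass, the Teager-Kaiser energy operator, rectification and
    low-pass smoothing; bursts are marked by an adaptive double threshold
    (rest-statistics magnitude criterion plus a per-muscle duration criterion);
    step-like events are registered from the normalized flexor-extensor
    relative-difference signal; stimulation-locked 25 ms MEP epochs are
    partitioned into early/middle/late response windows and summarised by peak
    counts, integrated EMG and peak-to-peak amplitude. Includes event-level
    precision/recall validation against annotation logs and a synthetic EMG
    generator with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
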