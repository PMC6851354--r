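# scalphfo

Automated detection and clinical validation of high-frequency
oscillations (HFO, 80–500 Hz) in scalp EEG and intraoperative
electrocorticography, for epilepsy research groups who want a fully
scripted, reproducible version of the scalp-HFO biomarker workflow:
from EDF recordings to per-hemisphere HFO rates to the statistics that
relate those rates to seizure frequency and surgical outcome.

## What it implements

**Detector.** A three-stage automated HFO detector per clean NREM
epoch and bipolar channel:

1. band-pass filtering (ripple 80–250 Hz or fast-ripple 250–500 Hz)
   and candidate detection where the Hilbert envelope exceeds a
   background-adaptive threshold
   `Th_amp = mean + k·SD` of the envelope over oscillation-free
   baseline (selected by Stockwell spectral entropy; default k = 3,
   minimum 4 cycles, 10 ms merge gap);
2. time–frequency validation on the Stockwell transform
   (frequency-scaled Gaussian window, σ_t = 1/f): accept only isolated
   in-band spectral peaks, rejecting filtered spikes, filter-skirt
   leakage and broadband muscle bursts;
3. cross-channel rejection of events co-occurring on >80% of channels.

**Rates and clinical statistics.** Accepted events become per-channel
rates (events per clean NREM minute), aggregated per hemisphere (mean
for scalp, max for ECoG). The clinical layer computes the ROC-optimal
rate threshold (accuracy-maximizing observed rate under strict ">"
classification), the confusion matrix with PPV = TP/(TP+FP),
NPV = TN/(TN+FN), accuracy = (TP+TN)/N and Wilson score intervals, the
ordinary-least-squares severity regression
`log10(rate) = a + b·log10(seizure frequency)` (seizure freedom mapped
to 0.05 seizures/month), Wilcoxon signed-rank / rank-sum contrasts and
the pre/post concordance chi-squared.

**Synthetic EEG with ground truth.** `make_recording()` generates
1/f³ sleep background plus white amplifier noise at a stated density
(2.3 nV/√Hz for a low-noise amplifier, 21 nV/√Hz for a commercial
device), injected ripple/fast-ripple bursts with known times, and
spike artifacts; `make_cohort()` generates power-law severity cohorts.
Every detector and statistics claim in the test suite is scored
against this ground truth.

## Worked example

Simulate a recording, detect ripples, and score against ground truth:

```r
library(scalphfo)

sim <- make_recording(recording_spec(duration_s = 600,
                                     channel_labels = c("C4-P4", "C3-P3"),
                                     seed = 7))
events <- detect_hfo(sim$recording, band = "ripple")
table(events$status)
#>               accepted rejected_cross_channel            rejected_tf
#>                     38                      2                     20

es <- clean_epochs(sim$recording)
channel_rate(events, "C4-P4", es$clean_minutes)
#>   channel band n_events clean_minutes rate
#> 1   C4-P4 <NA>       16            10  1.6

score_detection(events, sim$truth, band = "ripple")$sensitivity
#> [1] 0.95
```

The 20 `rejected_tf` events are the injected spike artifacts and noise
excursions the Stockwell validation stage removed, and 2 events that
happened to co-occur on both channels were flagged by the cross-channel
stage; the accepted-event rate (1.6/min on C4-P4) tracks the injected
2/min within counting error and the cross-channel losses on this small
two-channel montage.

Reproduce the clinical-table statistics in one call:

```r
reproduce_table1()
#> Clinical table metrics (n = 19 recordings)
#>   ROC rate threshold : 0.25 HFO/min (14 positive)
#>   confusion          : TP 12  FP 2  FN 1  TN 4
#>   PPV / NPV / acc    : 86% / 80% / 84% CI [62% 94%]
#>   severity regression: R^2 = 0.80 (log10-log10, p = 2.8e-07) [raw-scale R^2 = 0.88]
#>   hemisphere test    : p = 0.0003 (signed rank)
#>   active vs free     : p = 0.0085 (rank sum)
```

The packaged table (`inst/extdata/table1.csv`) holds the 19 scalp
recordings of the study cohort — affected/non-affected hemisphere HFO
rates, seizure frequency per month and ILAE outcome class — and the
numbers above are recomputed from it at call time: 14 of 19 recordings
exceed the 0.25 HFO/min threshold, 12 of them in active epilepsy, and
the affected-hemisphere rate explains 80% of the log-scale variance in
seizure frequency.

A thin command-line wrapper (`inst/cli/hfoscan.R`) exposes
`simulate`, `detect` and `reproduce-table1` over a YAML config with a
mandatory seed.

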