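---
title: "Interictal biomarker co-occurrence analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interictal biomarker co-occurrence analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeripples)
```

## The problem

In drug-resistant focal epilepsy, surgery succeeds when the epileptogenic
zone (EZ) is removed. The clinical stand-in for the EZ is the seizure-onset
zone (SOZ), which requires waiting for seizures during invasive monitoring.
Interictal (between-seizure) biomarkers on intracranial EEG promise to
delineate the EZ without that wait: epileptiform spikes are sensitive but
unspecific; high-frequency oscillations — ripples (80–250 Hz) and fast
ripples (250–500 Hz) — are more specific but sparse. Fast ripples are seen
in only a fraction of patients, which caps their clinical usefulness. A
natural compromise is the *temporal co-occurrence* of spikes and ripples
(a spike "on" a ripple), which is observable in essentially all patients.

This package implements the full analysis chain for that question: detect
spikes and HFOs per contact, classify them by co-occurrence into eleven
categories, quantify each category's ability to localize the SOZ and
resected area (RA), and relate the *resection ratio* of each category to
surgical outcome. A synthetic-cohort generator with known ground truth
makes every stage testable without patient data.

## Event detection

**HFOs** are detected per channel with a Hilbert-envelope detector: the
trace is band-pass filtered (zero-phase FIR, 256 taps), and candidate
events are maximal runs where the analytic-signal envelope exceeds
`mean + threshold_sd × SD` of the whole-segment envelope (`threshold_sd = 5`
by default; a median/MAD variant is available for heavily contaminated
segments). Runs closer than 10 ms merge; candidates shorter than 6 ms or
with fewer than 4 oscillations are discarded. All parameters are exposed in
`hfo_params()`; the defaults follow common practice for Hilbert/energy
detectors in this field and are the package's own choices, fully
configurable.

*Counting oscillations.* We count rectified-signal peaks above half the
event's envelope maximum, over the event's half-maximum envelope extent.
Band-pass filtering widens a burst's envelope by roughly one oscillation
cycle, so one counted peak is subtracted as a smearing allowance. With this
convention a clean 3-cycle burst counts ~3 and is rejected at the default
`min_oscillations = 4`, while 6-cycle bursts count ~6 and pass — which is
what visual review would conclude from the filtered trace.

**Quality control** (`qc_hfo()`) mirrors expert review: an event is accepted
if its in-band spectrum shows an isolated interior peak (the "island" in the
time–frequency plane) *or* it has at least four oscillations, and it is
rejected when a sharp transient in the raw trace coincides with fewer than
four oscillations — the signature of Gibbs ringing from filtering steps or
spikes. Rejections are labelled `rejected_gibbs` when the in-band spectrum
is concentrated at the low band edge (filtered step/spike) and
`rejected_blob` for broadband events (artifactual "elongated blobs").

**Spikes** are detected by a deliberately transparent stand-in: after
common-average referencing, DC removal, 1–70 Hz zero-phase band-pass and a
60 Hz notch, samples where the mean of the robust amplitude and slope
z-scores exceeds 5 seed events, merged within a 200 ms refractory window and
clamped to 20–200 ms. This stand-in is *not* equivalent to validated
commercial detectors; external spike annotations can be imported as CSV
instead (`read_event_table()`).

## Co-occurrence classification

Two events on the same channel co-occur when their peak times differ by at
most 50 ms (closed interval; the boundary counts). Clusters are connected
components of this relation — single linkage, so a chain spike–ripple–fast
ripple at 0/40/80 ms is one cluster. This is the only order-independent
reading of a pairwise window rule; peak times (rather than interval overlap)
are used because they are the detectors' most stable landmark. The eleven
categories are: All S / All R / All FR (every event of a type), the seven
exclusive compositions (S only, …, S+R+FR), and S+HFO (spike with at least
one HFO). Both per-cluster and per-event tallies are reported; the headline
`count` column uses events for the All-* categories and clusters for the
compositions. Rates are counts divided by the analyzed duration in minutes,
and channels without events participate with rate 0.

## Localization and outcome evaluation

**ROC conventions.** A contact is predicted "inside" when its rate strictly
exceeds the threshold; condition positives are contacts inside the RA (or
SOZ). The threshold set is every observed rate plus both extremes, so the
curve always reaches (0,1) and (1,0). Sensitivity at fixed specificity
(85/90/95%) uses the achievable operating point with the smallest
specificity at or above the level, without interpolation — rate thresholds
are discrete. The restricted-specificity pAUC integrates sensitivity over
FPR ∈ [0, 0.15] (trapezoid, with linear interpolation of the polyline at the
boundary), normalized by the maximum area 0.15.

**Two chance levels.** One convention in the literature takes chance as half
the maximum (0.075 raw, 0.5 normalized). A truly uninformative classifier
traces the diagonal, whose restricted area is 0.15²/2 = 0.01125 (0.075
normalized). The two differ because half the maximum is not the diagonal's
area on a restricted range. `pauc_chance()` computes both; plots draw both
reference lines. We flag the discrepancy rather than resolve it.

**Resection ratio.** For a biomarker, the ratio of its total rate carried by
resected contacts to the total over all contacts — 1 means everything was
removed. Patients without the biomarker have an undefined ratio and are
excluded from that biomarker's outcome analysis (exclusions are counted and
reported). Outcome prediction treats good outcome (Engel I) as the positive
class and "ratio strictly above threshold" as a positive prediction; a ratio
of exactly 0.5 predicts poor. The operating point maximizes Youden's J
(ties broken toward specificity), and the full suite — sensitivity,
specificity, PPV, NPV, markedness, FPR, accuracy — is evaluated there.
Leave-one-out cross-validation refits the threshold in every fold and
summarizes metrics as median (IQR); this characterizes the stability of the
operating point rather than held-out prediction, and is documented as such.
The pseudo-prospective variant fixes the cut-off at 0.5 with no fitting.
Association between biomarker removal and outcome is tested with Barnard's
exact unconditional test (pooled-z ordering, 1000-point nuisance grid) —
the common, well-defined variant of the test.

## The synthetic cohort

The generator defines the study conditions under which the pipeline is
validated:

* background: 1/f pink noise (α = 1), 20 µV RMS, 2 kHz sampling;
* baseline channel rates: 1.3 spikes/min, 0.9 ripples/min, 0.15 fast
  ripples/min — the magnitudes typical of interictal cohorts of this kind;
* co-occurrence planned at generation time: 11% of spikes arrive with a
  ripple, 2% with a fast ripple, 2% with both, and 5% of ripples with a fast
  ripple, so category ground truth is exact (emergent co-occurrence from
  independent processes would leave no exact truth to score against);
  companions are jittered uniformly within ±50 ms of their anchor;
* a rate doubling (`inside_multiplier = 2`) on SOZ/RA channels, the contrast
  magnitude this analysis is designed to detect;
* SNR 5, defined as the event's peak amplitude over √2 times the background
  RMS in the event's band (i.e. the event has 5× the amplitude of an
  equal-power in-band sinusoid) — the literature reports no amplitude
  statistics, so this default is the package's own and is stated here;
* cohorts of 40 patients (26 good outcome), 16 channels × 10 min each, with
  per-patient rate scaling U(0.5, 2); outcome is tied to ground truth by
  choosing the resected set so the S+R resection ratio lands on the designed
  side of 0.5, then flipping labels with probability 0.1.

Sixteen channels and 10 minutes are desk-scale choices; clinical recordings
have on the order of 100 contacts and anywhere from minutes to hours of
usable sleep data. Anchors on a channel keep a 0.25 s dead time so planned
clusters cannot merge, and events stay 100 ms clear of segment edges
(filter transients). What the generator does *not* emulate: sleep
architecture and state-dependent rate drift, seizures, artifacts beyond the
sharp transients used for QC testing, spatially correlated noise across
contacts, and electrode-specific spectra. Passing tests therefore show the
*analysis* is correct under its assumptions, not that the detectors would
meet the same numbers on clinical recordings.

## Numerical choices and degenerate inputs

* Event times are seconds from recording start, 0-based, intervals
  half-open; a co-occurrence latency of exactly 50 ms counts (closed
  window).
* `window = 0` degenerates to exact-tie grouping; very large windows give
  one cluster per channel.
* Single-class channel labels (nothing resected, or everything) make a
  patient's ROC undefined; such patients are skipped with a message.
  LOO folds left with one outcome class are skipped and logged.
* PPV/NPV with empty denominators are `NA`; markedness then propagates
  `NA`.
* The EDF writer uses a symmetric physical range per signal and the full
  16-bit digital range; round-trip error is bounded by one quantization
  step. Recordings are zero-padded to whole 1 s records.
* Envelope statistics use the whole segment (no epoching); segments must be
  at least 1 s for a meaningful baseline.
* Barnard's nuisance grid excludes the endpoints 0 and 1 (where the
  likelihood degenerates); the pooled z is defined as 0 when the pooled
  proportion is 0 or 1.

## Problem sizes used in the shipped checks

The test suite and acceptance script exercise the pipeline at sizes chosen
to keep a full run on one CPU comfortable: oracle equivalences at n ≤ 50
events (clustering) and n ≤ 200 units (ROC), detector recovery on 4-channel,
5-minute patients, rate-contrast power over 100 simulated 26-patient
cohorts with a 200-cohort null calibration, and outcome recovery on
40-patient cohorts. These sizes are stated here so readers know what the
reported numbers summarize.

## Known limitations

The spike stand-in is a convenience, not a validated clinical detector; its
sensitivity/precision figures hold on synthetic data only. Cross-channel
co-occurrence and propagation, coupling to slow waves, and multivariate
combinations of biomarkers are out of scope. The LOO summary refits the
operating point per fold, so its medians describe stability, not
generalization. Real cohort effect sizes (e.g. the published headline
accuracies) depend on patient data this package does not ship and are not
reproduced here.
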