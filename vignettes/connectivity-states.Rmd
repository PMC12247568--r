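---
title: "Connectivity states from phase-locked EEG parcels: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity states from phase-locked EEG parcels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`phasestates` treats resting-state brain dynamics as switching among a
small number of recurring *connectivity states*: configurations of
cortical parcels whose alpha-band oscillations are phase-locked at a
non-zero lag. The pipeline is

1. **Phases.** Each parcel time course is convolved with complex Morlet
   wavelets on a grid from 8 to 12 Hz in 0.5 Hz steps. The cycle count
   interpolates linearly from 4 cycles at 8 Hz to 6 at 12 Hz, which keeps
   the temporal envelope roughly constant (σ_t ≈ 80 ms) across the band.
   The phase is the argument of the complex output, the amplitude its
   modulus.
2. **ciPLV.** For each unordered parcel pair and each 300 ms window
   (hopped by 100 ms), the corrected imaginary phase-locking value is
   |Im(S)| / sqrt(1 − Re(S)²) with S the mean phase-difference phasor
   over the window's T = ⌊0.300·srate⌋ samples. The value is 1 only for
   perfect locking at ±π/2 lag; locking at zero lag — the signature of
   source leakage rather than genuine interaction — maps to 0. Per-bin
   values are averaged over the nine frequency bins (see *Open choices*).
3. **Dynamic graph.** Per window, exactly ⌊0.10 · P(P−1)/2⌋ pairs with
   the largest ciPLV become edges of a binary undirected graph. Sparsity
   emphasises the most robust connections; the exact-count rule keeps
   every window comparable.
4. **States.** k-means (Euclidean) on the windows' binary edge vectors,
   best of 10 seeded restarts by within-cluster sum of squares. Centroid
   entries are mean edge occupancies in [0, 1]. Group-level states
   re-cluster the pooled subject centroids. Backfitting labels each
   window with its nearest centroid (ties to the lowest index), and the
   label sequence yields coverage, the empirical first-order transition
   matrix (within contiguous artifact-free segments only), and mean
   dwells.
5. **Statistics.** Coverages are compared with the Wilcoxon signed-rank
   test (exact null for n ≤ 25 untied pairs, normal approximation with
   continuity correction otherwise) for connectivity states and paired t
   for microstates; across-day reliability uses the two-way consistency,
   single-measure ICC, whose degrees of freedom are (n−1) and
   (n−1)(d−1); families of comparisons are Bonferroni-corrected.

The sensor-level microstate module mirrors the classical analysis:
polarity-invariant modified k-means, where assignment maximises squared
spatial correlation and each map update is the dominant spatial direction
of its assigned samples; the best restart maximises global explained
variance. It exists as a face-validity companion, not as the package's
main object.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band | 8–12 | Hz | alpha: narrowband, motor-relevant, time resolution acceptable |
| wavelet cycles | 4→6 | — | ~80 ms envelope across the band |
| window | 300 | ms | long enough for a stable phasor mean at T = 38 samples, short enough to track state switching |
| hop | 100 | ms | microstate-scale time resolution; 200 ms window overlap |
| edge fraction | 0.10 | — | sparse graphs, exact edge count per window |
| k (states) | 4 | — | the canonical microstate-literature granularity; the elbow rule explores alternatives |
| n_init | 10 | — | restart count for every k-means level |
| quality gate | <7 bad channels, >180 s clean per run | — | cumulative, not contiguous, clean time |

## The synthetic generator

`synthetic_spec()` defines the study conditions the tests run under:
20 parcels at 128 Hz for 5 minutes, four states switching as a
first-order Markov chain with 600 ms mean dwell at 100 ms resolution,
von Mises phase jitter with concentration κ = 20, and a 3:1
signal-to-noise variance ratio against 1/f background noise. Each state
is realised by a 6-parcel subnetwork split 3 + 3 between phase offsets 0
and π/2, so all nine planted edges carry a π/2 lag (maximally visible to
ciPLV) while within-group pairs are zero-lag and hence suppressed — a
deliberate cancellation check built into the ground truth.

Phases are generated as continuous dynamics, not piecewise overrides: a
parcel's base phase advances at its intrinsic frequency (carrier 10 Hz
plus an individual detuning drawn uniformly from ±2 Hz) with random-walk
noise, and is pulled toward the active state's driver-plus-offset with a
10 ms relaxation constant while the parcel is coupled. When its state
ends, the coupling gain decays with a 45 ms time constant instead of
vanishing, so an outgoing subnetwork desynchronises the way coupled
oscillators do. These two constants were chosen so that the generated
signals realise the intended ground truth — instantaneous phase jumps
produce broadband artifacts that the wavelet stage smears over ±150 ms,
which is a property of the analysis, not of the planted process.

What the generator deliberately does **not** emulate: volume-conduction
leakage mixing (parcel signals are leakage-free by construction; ciPLV's
zero-lag suppression is exercised via the within-group zero-lag pairs
instead), non-stationary amplitude dynamics, inter-subject anatomical
variability, and any sensor-to-source inverse step. Passing tests
therefore show that the pipeline recovers phase-locked switching
structure under realistic noise — not that source reconstruction of real
recordings is accurate.

## What recovery can and cannot achieve

With 600 ms geometric dwells, a 300 ms window and ~±150 ms of wavelet
smoothing, roughly a third of analysis windows straddle a state
boundary. Their phase content genuinely interpolates two states: the
majority state's edges weaken and the outgoing state's edges linger. Two
consequences, both visible in the test suite:

* Coverage and centroid recovery are robust (the planted edge sets come
  back essentially exactly, coverages within a few percentage points),
  because errors in transition windows largely cancel between the two
  parent states.
* Per-window assignment accuracy saturates below perfect even with the
  *planted* centroids as classifier — transition windows are
  intrinsically ambiguous at this window length. The acceptance test
  asserts the 90 % target and documents the shortfall rather than
  relaxing it.

The same transition mass creates a genuine extra "blend" cluster in edge
space. This is why the elbow of the inertia curve can indicate one state
more than the planted count when many short dwells occur — mirroring, at
small scale, the empirical finding that resting EEG supports both
4-state and richer solutions.

## Numerical and design choices

* **Windows.** T = ⌊window·srate/1000⌋ samples; window k starts at
  sample round(k·hop·srate/1000); windows touching invalid samples are
  dropped entirely. Runs are bit-reproducible given seeds.
* **ciPLV degenerate case.** |Re(S)| = 1 (perfect zero-lag lock) returns
  0, consistent with the zero-lag suppression the measure exists for.
  The printed formula is signed; the package reports the magnitude (the
  `signed = TRUE` variant exposes the sign for null-distribution work).
* **Frequency aggregation.** ciPLV per 0.5 Hz bin, arithmetic mean over
  bins (default). Pooling phase differences across bins before the ratio
  is available (`aggregate = "pooled"`); it slightly deepens the
  planted-vs-background separation but is less standard.
* **Thresholding ties.** Broken toward the lower pair index —
  deterministic, and permutation-equivariant in distribution.
* **k-means engine.** `stats::kmeans` behind a seeded restart loop that
  draws k *distinct* data rows as initial centers (duplicate binary rows
  otherwise break initialisation); when exactly k distinct patterns
  exist the patterns themselves are the provable optimum and are
  returned directly. Best restart by total within-SS.
* **Elbow rule.** Maximum discrete curvature (second difference of
  inertia). The distance-to-chord rule is available but drifts toward
  larger k when the grid extends far into the flat tail; measured on
  planted data the curvature rule localises the bend better.
* **Label alignment.** Exhaustive optimal assignment over permutations
  for k ≤ 8 (exact), greedy beyond; polarity-invariant matching for
  microstate maps.
* **Sign-flip averaging.** The dominant orientation is the leading
  singular vector of the parcel's normal matrix, sign fixed by the
  majority of normals (canonical largest-component-positive on ties).
  Under a global negation of normals and data the parcel course is
  reproduced up to sign — exactly the equivalence class that
  phase-difference measures live in.
* **Quality gate.** ">180 s artifact-free" is cumulative. "Best four of
  five sessions" ranks by total clean seconds (RS1+RS2), ties to the
  earlier session; dropping day one when all five pass is available as
  `drop_first_if_all_pass`.
* **Group clustering input.** Pooled subject centroids (k rows per
  subject), not pooled windows — the same second-level structure as the
  group microstate procedure; RS1 and RS2 are clustered jointly by
  default so state labels correspond across tasks, with `per_task`
  clustering as the alternative.
* **Microstate segmentation.** All samples, no GFP-peak subsampling and
  no temporal smoothing by default (both exist as options); band
  defaults to the broadband 1–40 Hz convention with the alpha band as an
  option.

## Problem sizes in the tests

The unit tests run the generator at 10–100 s durations and the full
acceptance property at the stated 5-minute, 20-parcel condition; the
statistics null calibration uses 10,000 simulated n = 24 datasets. These
sizes are the package's chosen test design; the full 150-parcel
configuration runs through the identical code path (pair chunks bound
memory) and is exercised at reduced depth.

## Known limitations

* Transition-window ambiguity caps per-window assignment accuracy at
  this window length; metrics that average over windows are much more
  stable than per-window labels.
* The ICC is the consistency form only; absolute-agreement reliability
  is out of scope.
* The BrainVision reader covers INT_16/INT_32/IEEE_FLOAT_32 and ASCII
  layouts without marker interpretation; EDF is not read.
* No inverse solution: the package consumes vertex- or parcel-level
  source estimates as given.
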