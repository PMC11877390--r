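---
title: "Remote alcohol-consumption sensing from laser speckle videos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote alcohol-consumption sensing from laser speckle videos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement principle

When a coherent laser illuminates a rough surface (here, the skin over the
radial artery) the back-scattered light self-interferes into a granular
speckle pattern. With the camera deliberately defocused toward the far
field, a tiny *tilt* of the surface does not change the pattern — it
translates it rigidly across the sensor. The heartbeat tilts the skin
surface periodically, so the lateral position of the speckle pattern over
time is a remote, non-contact record of cardiac mechanics, comparable to a
phonocardiogram. Alcohol alters heart rate, beat amplitude and variability;
those alterations are imprinted on the displacement waveform, and a
classifier trained on waveform features can detect whether a person has
consumed alcohol without any before/after comparison.

The package implements the full computational chain:

1. **`speckle_sim`** — synthetic speckle videos with known ground truth;
2. **`vibrometry`** — displacement tracking by frame-pair cross-correlation;
3. **`preprocess`** — overlapping chunking and subject-wise splits;
4. **`features`** — a fixed registry of time-series descriptors and
   hypothesis-test filtering;
5. **`classify`** — label-merging schemes and a tuned gradient-boosted tree
   ensemble;
6. **`evaluate`** — confusion matrices, accuracy/precision/sensitivity/
   specificity/F1, ROC/AUC.

## The recording model

A recording is 6 s at 500 frames per second: 3000 frames at 2 ms
resolution. Cardiac motion lives in the 0.5–3 Hz band; motion artifacts
(posture drift, breathing-scale movement) sit below 0.5 Hz. The study
design is five subjects, each measured at five time points ("before
drinking", "0 min", "30 min", "60 min", "90 min"), five recordings per
time point — 125 recordings in total. (The source text's "125 videos per
subject" is arithmetically inconsistent with its own 5 × 5 × 5 layout; the
simulator exposes `recordings_per_state` so either reading is producible,
and the default follows the 125-total reading.)

## What the simulator states about the world

No recordings of human subjects are distributed, so the simulator *is* the
test bed, and its defaults are commitments, not tuning knobs:

- **Beat model.** Each heartbeat contributes a raised-cosine (Hann)
  displacement lobe. The lobe is smooth and band-limited — a deliberate
  idealization of the sharper, multi-component pulse of a real
  phonocardiogram. Its default width is 0.4 s, the scale of systole; this
  width also keeps >90 % of the non-DC signal power inside the 0.5–3 Hz
  band (asserted by a periodogram property test), which narrower lobes
  (e.g. 0.25 s) violate by pushing harmonics past 3 Hz.
- **Heart-rate variability.** Inter-beat intervals are drawn from a
  truncated-positive normal with mean `1/heart_rate_hz` and standard
  deviation `hrv_sd_s` (default 0.05 s).
- **X/Y coupling.** The cardiac signal drives a fixed unit direction
  (default (1, 0.4) normalized), so both axes carry correlated signal; the
  original analysis extracts both axes but does not specify their relation.
- **Artifacts.** A sub-0.5 Hz sinusoidal drift (default 0.5 px at 0.1 Hz,
  random phase and direction per recording) plus white displacement noise
  (0.05 px).
- **Alcohol states.** The baseline is 1.1 Hz heart rate and 2 px beat
  amplitude. Post-consumption states scale amplitude by 1.5/1.4/1.25/1.15
  and rate by 1.25/1.2/1.12/1.06 at 0/30/60/90 min — a monotone return
  toward baseline mimicking the reported linear decline of blood alcohol
  concentration from about 0.05 % to 0.025 % over the session. The true
  quantitative effect of alcohol on the speckle-derived waveform is not
  published; these are stated assumptions, configurable but fixed as
  defaults.
- **Speckle rendering.** One master field per recording is synthesized as a
  random-phase screen on a circular frequency support (a fully developed
  speckle model; grain size = field side / support diameter). Each frame is
  a crop of the master field translated by the cumulative shift — integer
  parts by pure indexing (exactly), fractional parts by bilinear
  interpolation — plus Gaussian sensor noise, quantized to 8 bits.

What a green test does **not** establish: the simulator has no tissue
optics, no pattern decorrelation, no rolling shutter, no subject-specific
physiology (all subjects share the per-state profiles; recordings differ
only through seeded beat timing, drift phase and noise). Accuracies on this
world say the *pipeline* works, not that the published human-subject
accuracies are reproduced — those depend on recordings that are not
available, and the package deliberately does not target them.

## Displacement tracking

Consecutive frames are correlated in the frequency domain (zero-mean,
normalized, circular). The correlation peak's offset is the inter-frame
shift, signed per axis in (−N/2, N/2]; cumulative position is the running
sum. Design choices:

- consecutive pairs rather than a fixed reference frame (matching the
  described processing; it also tolerates slow pattern decorrelation in
  real data);
- circular correlation is acceptable because true shifts are a few pixels
  against a 64 px frame;
- subpixel refinement by a per-axis three-point parabolic fit, clamped to
  ±0.5 px — cheap and adequate: on noise-free integer-shift videos
  recovery is *exact* (a designed property: integer rendering is pure
  indexing), and on fractional-shift videos with 2 grey levels of sensor
  noise the cumulative RMSE over 3000 frames stays ≤ 0.25 px;
- ties at multiple equal correlation maxima break to the smallest
  row-major index; constant frames raise an explicit error rather than a
  0/0;
- no windowing by default (speckle fills the frame); a Hann window flag
  exists for edge-dominated scenes.

## Chunking and the learning channels

Traces are sliced into windows of 256 frames with stride 32; trailing
partial windows are dropped (3000 frames → 86 chunks). Each chunk carries
four channels: X and Y cumulative position re-zeroed to the chunk's first
sample, and their first differences padded to full length by repeating the
first value. Re-zeroing removes inter-chunk offsets so chunks are
comparable; the difference channels then coincide with the per-pair shifts.
Splitting is subject-wise (leave one subject out) — overlapping chunks of
one recording are near-duplicates, so a random chunk-wise split leaks;
that mode exists behind a flag and warns.

## Features and selection

Eighteen descriptors per channel (72 columns): mean, median, standard
deviation, skewness, excess kurtosis, min, max, range, quantiles
0.1/0.25/0.75/0.9 (type-7 interpolation, bit-reproducible), RMS, mean
absolute change, lag-1 autocorrelation, signal energy, dominant frequency
and the fraction of non-DC power in 0.5–3 Hz. The registry implements
every named family of the original feature set plus band-aware spectral
descriptors; the enumerated source list also names variance, which is
omitted as a monotone duplicate of the standard deviation under
tree-based classifiers, keeping the registry at the stated 72 columns.
Degenerate values on constant channels are imputed to 0 with a warning, so
tables never contain missing values.

Selection tests each feature against the target labels with rank-based
tests (robust on heavy-tailed displacement features): Mann–Whitney U for
binary targets, Kruskal–Wallis for multiclass; features with p ≤ 0.05 are
kept. The raw-p rule follows the stated procedure; Benjamini–Hochberg FDR
control is available as `correction = "fdr"`. Selection is computed on
training rows only and applied frozen to validation rows.

**When selection happens.** The pipeline selects **once, on the five-label
training target**, and reuses the kept set for every label-merging scheme.
Two reasons. First, the original workflow selected features at the feature
stage and then merged labels "and retrained" — retraining only. Second,
per-scheme re-selection is provably degenerate in this world: under binary
scheme B the class boundary is non-monotone in signal amplitude (the
strongest state, "0 min", is on the "no alcohol" side), and a rank test
cannot see non-monotone relevance, so it discards exactly the informative
features (16/72 kept; held-out accuracy drops from ≈0.85 to ≈0.61, barely
above the majority rate). Per-scheme selection remains available via
`features$per_scheme = TRUE` in the run configuration.

## Classifier

A gradient-boosted decision-tree ensemble with a softmax objective —
binary is the two-class case with "alcohol" positive. No boosted-tree
package is assumed; the ensemble is implemented in C++ in the package:
histogram-binned features (≤64 quantile bins), exact greedy splits by
second-order gain with L2-regularized Newton leaf weights, one tree per
class per round. It is fully deterministic, which makes the surrounding
reproducibility guarantees checkable.

Hyperparameter search is seeded random search over the three parameters
the original optimization tuned: number of trees in [50, 500], depth in
[2, 8], learning rate log-uniform in [0.01, 0.3]; the objective is
accuracy on the held-out subject (matching the original single-split
design; a k-fold-over-subjects mode is the obvious extension and was left
out of scope). The search budget (default 50 trials) is not stated in the
source and is configuration-exposed; ties break to fewest trees, then
shallowest depth, then earliest trial — smallest model wins,
deterministically. Validation rows influence only the search objective,
never feature selection or tree fitting.

## Evaluation

Confusion matrices are oriented rows = true, columns = predicted, with
row-percentages beside raw counts — note the per-label "accuracy" shown in
such matrices is the per-class recall. The five binary metrics follow the
standard formulas, with zero-denominator cases reported as undefined
(`NA`) rather than raising errors; reported percentages round half away
from zero. ROC curves sweep thresholds over the unique scores with
trapezoidal AUC; multiclass problems are evaluated one-vs-rest per class
with an unweighted macro average.

## Numerical choices and degenerate inputs

- Seeds fan out from one master seed through an exact Lehmer step
  (multiplier 48271 mod 2³¹−1), so every recording, stage and search has a
  distinct reproducible stream and all derived seeds stay below 2³¹.
- Speckle master fields are scaled so the mean intensity sits at one
  quarter of full scale, leaving headroom for the exponential-like bright
  tail before 8-bit clipping; the intensity coefficient of variation > 0.3
  is asserted (a developed pattern, not a flat field).
- The parabolic subpixel fit returns 0 when its denominator vanishes
  (plateau peak), and wraps its neighborhood circularly at frame edges.
- Quantiles use type-7 interpolation; kurtosis is excess kurtosis;
  autocorrelation at lag 1 uses the biased (divide-by-total-energy) form.
  All three are stated so values are bit-reproducible.
- A run configuration rejects unknown keys (including inside nested
  blocks) so a typo cannot silently revert a stage to defaults.

## A worked run

```r
library(speckledrink)
cfg <- default_config()
cfg$recordings_per_state <- 2   # desk-scale study
cfg$trials <- 8                 # desk-scale search budget
res <- run_pipeline(cfg)
round(res$accuracies, 3)
#>        five three_case1 three_case2    binary_A    binary_B    binary_C
#>       0.812       0.849       0.899       0.899       0.885       0.942
print(res$reports$binary_C)
```

The ordering — binary schemes above three-label schemes above the
five-label problem — reproduces the central qualitative finding that
merging labels trades temporal resolution for accuracy; the strongest
contrast (before drinking vs. any consumption) is also the most accurate,
matching its intended screening role where sensitivity is the priority.

## Known limitations

- The synthetic world encodes alcohol effects purely as amplitude and rate
  scalings; shape changes, subject heterogeneity and measurement dropouts
  are absent, so absolute accuracies here are optimistic relative to human
  data.
- The data-augmentation step mentioned in the source beyond window overlap
  is undescribed; an equivalent cannot be implemented and none is.
- The vibrometry stage assumes rigid pattern translation; strong
  decorrelation (large tilts, skin deformation) would lower peak heights —
  the per-pair `peak_height` column is exported precisely so users can
  screen for it.
- Recording-level aggregation (majority vote over a recording's chunks) is
  not the primary metric; chunk-level accuracy is, because the chunk is
  the classification unit throughout.
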