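---
title: "Methods: on-chip style neural signal processing in neurocodec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: on-chip style neural signal processing in neurocodec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocodec)
```

`neurocodec` is a software model of the digital signal-processing engines
found in modern implantable neural recording front ends: spike detection,
action-potential (AP) compression, local-field-potential (LFP) compression,
fixed-point filtering, raster packetization and spike sorting.  Every engine
is implemented bit-exactly where the hardware is bit-exact (codecs, FIR
arithmetic) and numerically where the hardware is approximate (sorting).
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic benchmarks do and do not demonstrate.

## The signal model and the synthetic generator

The universal input is a `neuro_recording`: an integer matrix of ADC counts,
channels by time, at `fs = 20` kHz and 9-bit signed resolution by default
(one LSB corresponds to about 3.9 uV at a +/-1 mV input range).  The
generator superimposes three sources:

* **Spikes.** Each channel-template pair fires as an independent Poisson
  process.  Templates are 64-sample biphasic waveforms whose steep
  depolarization peaks 33 samples into the window; this mirrors the
  detector's 32-sample pre-buffer, so a captured event window coincides with
  the inserted window.  Default amplitudes (65-95 counts, i.e. roughly
  250-370 uV) are in the range of large nearby units.  The default aggregate
  rate is 60 spikes/s per channel (20 Hz for each of three templates), the
  reference operating point used throughout the package.
* **Background noise.** Additive Gaussian noise in ADC counts before
  quantization, default `noise_sd = 2` counts (~8 uV rms) — a quiet but
  realistic cortical recording.  This is a surrogate for thermal plus
  multi-unit background; it is spectrally white, which real background is
  not.
* **LFP.** Band-limited (< 300 Hz, 4th-order Butterworth) Gaussian noise
  mixed across channels with exponentially decaying weights
  `w[c, j] = mixing^|c - j|` (rows normalized to unit variance).  This gives
  the inter-channel correlation structure that spatial decorrelation
  exploits, with correlation decaying along the probe — without claiming
  biophysical fidelity.  AP-regime fixtures set `lfp_amplitude = 0`, because
  the AP signal path is high-pass filtered at 300 Hz in hardware.

Overlapping spikes superimpose linearly and the ground truth records both
onsets.  All randomness is fixed by `seed`; identical configurations are
byte-identical.

What passing tests on this generator show: exact codec inversion, correct
detector logic, and parameter recovery under controlled conditions.  What
they do not show: performance on real electrode noise (colored spectra,
movement artifacts, electrode drift, bursting non-Poisson units, waveform
non-stationarity).  Published benchmark datasets are needed for those
claims, and the file-based interface (`write_recording`/`read_recording`)
exists so such data can be dropped in.

## Two-stage spike detection and the adaptive threshold estimator

The nonlinear energy operator `psi[n] = x[n]^2 - x[n-1] x[n+1]` amplifies
transients quadratically.  The adaptive threshold estimator re-estimates
once per 64-sample window (configurable) from two statistics:

* a **noise level**: single-pole exponential smoothing of `|psi|` (and of
  `|x|` for the amplitude stage) with `alpha = 1/64` per sample — the
  cheapest hardware-plausible low-pass; one window's isolated impulse is
  attenuated by more than 4x;
* a **firing-rate proxy**: the count of sign-bit changes of `psi` in the
  previous window, compressed as `floor(log2(zc + 1))`.

The combination rule is a design choice of this package (the hardware
description names the inputs, not the formula):

`threshold = max(floor, k * noise * (1 + beta * log_rate))`

with defaults `k_neo = 8`, `k_amp = 4`, `beta = 0.125`, `floor = 1`.  It is
monotone nondecreasing in both inputs and reduces to the classic
`k * noise` rule at low rates.  Stage 1 applies the same machinery to `|x|`
with its own multiplier; whether the hardware's first stage shares
parameters with the estimator is unspecified, so the two multipliers are
independent knobs.  Thresholds are causal (window `w` uses statistics
through window `w - 1`); the first window warm-starts from its own mean so
recordings do not begin with a burst of false positives.

A detection fires where both stages exceed threshold.  The detection
instant is then refined to the local NEO energy peak within an 8-sample
lookahead, so the event window (32 samples before the instant, 32 from it
onward) captures the full depolarization; a 64-sample refractory lockout
separates events.  Consequence: ground-truth spikes closer than 64 samples
to their predecessor merge into one event, so recall is scored with a
one-window matching tolerance.

## Intra-channel AP compression

**Lossless.** Second-order DPCM (`r[i] = s[i] - 2 s[i-1] + s[i-2]`, two raw
warm-up samples) concentrates band-limited signals far below their raw
entropy; residuals are zigzag-mapped to non-negative integers and coded by
one of two backends:

* **Golomb-Rice** (`M = 2^k`): quotient in unary, remainder in `k` bits.
  `k` adapts every 256 symbols from the previous block's zero fraction via a
  monotone 8-level lookup derived from the geometric-source optimum
  `2^k ~ mean * ln 2`; the decoder mirrors the adaptation from its own
  output, so no side information is sent.
* **Semi-adaptive arithmetic coding**: a 32-bit integer range coder with a
  *frozen* symbol table trained offline (here: on the stream being coded, or
  on any representative segment shared across channels).  The table is 1024
  16-bit counts — explicit symbols 0..1022 plus an escape coded with a
  12-bit literal — quantized to a 32768 total with a floor of one, exactly
  2048 bytes serialized.  Freezing the table removes the per-symbol
  adaptation machinery that dominates hardware cost, at a small SSR price.

**Near-lossless.** Only detected spikes are preserved: the stream becomes
alternating frames of (zero-run length, 64-sample spike).  The run length
is split bitwise into two 8-bit components, or three when it exceeds
2^16 - 1, selected by a one-bit frame flag (flags are stored as plain bits
ahead of the entropy-coded symbol stream, which keeps the two backends
interchangeable).  Spike samples are DPCM2-coded with a zero history inside
each frame so frames decode independently.  Everything between spikes
decodes to zero — that is the documented information loss; spike waveforms
and onsets reconstruct exactly.

The space saving ratio is `100 * (1 - compressed / original)` with
`original = n_samples * bit_depth`.  By default the 6-byte stream header
and the (hardware-resident, SRAM-shared) symbol table are excluded from the
accounting; `payload_nbits` counts flag bits, warm-up bits and entropy
payload.

## Cross-channel LFP compression

Each 8-channel group is first temporally decorrelated with first-order DPCM
(the cross-channel engine uses first differences, not DPCM2).  Every child
channel is then predicted from its parent's residuals:
`e_child[n] - round(gamma * e_parent[n])`, the one-tap mode; multi-tap
prediction is excluded as not worth its cost.  The closed form

`gamma = sum(e_c e_r) / sum(e_r e_r)`

over a training segment minimizes residual energy, the proxy for coding
length; segment lengths of 1000-2000 samples are enough for gamma to
stabilize.  Numerical choices that make the pipeline exactly invertible:

* gamma is quantized to **Q1.14** fixed point (1 sign, 1 integer, 14
  fraction bits; quantization error <= 2^-15) and carried in the stream, so
  encoder and decoder use identical integer arithmetic;
* the prediction uses round-half-away-from-zero, mirrored in the decoder.

The channel chain is a **minimum spanning tree** over the complete channel
graph — this guarantees no closed loops — with edge weight the per-sample
residual energy after optimal gamma, symmetrized by taking the cheaper
direction (the hardware description never names the weight; energy is the
natural choice given the energy-length relation).  The root is the smallest
channel index, matching the alignment convention, and Prim's construction
breaks ties toward lower indices so training is deterministic.  Children
encode in topological order; residuals go through the zigzag map and the
block-adaptive Golomb backend.

## Fixed-point FIR filterbank

Sixteen parallel channels, 16 taps of signed 16-bit coefficients, and a
26-bit accumulator: `y[n] = sat26(sum c_i x[n-i])` with zero pre-history.
With 9-bit inputs every product is below 2^24 and the 16-term sum below
2^28, exactly representable in doubles, so the model clamps only the final
sum at `+2^25 - 1` / `-2^25` — one accumulator, one saturation point; no
per-product clamping, and no output rounding/shift stage is modeled because
none is specified.  Below saturation the filter equals plain convolution.

## Spike sorting

Detected waveforms are aligned at the maximum first-difference sample,
placed at index 20 of the 64-sample window (ties to the earliest sample;
out-of-window samples zero-padded).  Index 20 leaves room for the full
depolarization and repolarization; any fixed index works if used
consistently.

Two feature extractors share the projection (`mac_project`, a blocked
matrix product whose result is block-size independent — the software
contract of a hardware multiply-accumulate engine):

* **PCA** (<= 10 features): top principal axes of the centered spike
  matrix, sign-fixed so the largest-magnitude loading is positive.
* **Discriminative samples / "adaptive filter"** (<= 7 features): sample
  positions ranked by the between- over within-class variance ratio of a
  provisional clustering, emitted as a sparse 0/1 projection.  The precise
  hardware AF algorithm lives in prior work; this supervised selection
  reproduces its intent (few, cheap, discriminative taps).

Clustering is k-means with k-means++ seeding, five restarts (best total
within-cluster sum of squares), Lloyd iterations to convergence, and the
cluster count chosen by mean silhouette width over `k = 2..8` — the cap of
8 clusters is enforced.  Automatic selection recovers well-separated point
masses; on realistic fixtures, overlap-corrupted waveforms can form small
extra clusters, so pipelines that know the unit count may pass `k`
explicitly (the end-to-end benchmarks sort with the known template count).
Per-cluster covariances get a ridge of `1e-3 * trace / d` so Mahalanobis
classification is always well-posed.  Assignment is minimum Euclidean or
Mahalanobis distance, ties to the lowest cluster id; on anisotropic
correlated clusters Mahalanobis is measurably better, which is why the
engine supports it despite the extra cost.

Sorting accuracy is scored under the optimal one-to-one cluster-to-class
assignment (exhaustive over permutations — exact for <= 8 clusters).

## Pipeline commands

`run_command()` mirrors a command-driven control unit: C1/C2 record or
stream raw data, C3/C4 run the intra-/cross-channel codecs, C5/C6 the FIR
filterbank with different sinks, C7 the spike raster (one frame per 20 kHz
tick, empty frames header-only), C8/C9 report or update the adaptive
thresholds.  The hardware distinctions that are pure plumbing (SRAM vs SPI
sinks) collapse to options of shared handlers.  The raster byte format (1
header byte, 4-byte tick, channel list) is self-consistent but not
bit-compatible with any chip.

## Problem sizes and reproducibility

The test suite and the acceptance script generate all data in code.  The
headline near-lossless SSR is computed on a 60 s single-channel recording
at the reference operating point (1.2 million samples, ~3600 spikes);
lossless round-trip properties run on a hundred short randomized
recordings; sorting benchmarks use 15 s three-unit fixtures (~300-450
spikes).  Every stochastic step takes an explicit seed, and equal seeds
give byte-identical results.

## Known limitations

* The threshold-calculator formula, the RLE component widths, the MST edge
  weight and the AF algorithm are design choices where the hardware
  description is silent; each is isolated behind a parameter or a small
  function so alternatives can be swapped in.
* Gaussian white background noise flatters entropy coding slightly relative
  to colored real noise; the reported synthetic SSR figures are for the
  generator's regime, not for any published dataset.
* No lossy transform coding, no multi-tap spatial prediction, no online
  cluster adaptation, and no modeling of the analog front end, power or
  timing.
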