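---
title: "Probabilistic decoding of behavior from calcium imaging: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic decoding of behavior from calcium imaging: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caldecode)
```

## The problem

Miniscope calcium imaging reports the activity of hundreds of neurons as
slow fluorescence transients sampled at ~30 Hz. Because a transient only
indirectly reflects spiking — single spikes may be invisible, bursts merge
into one envelope, and exact spike times are unknowable at this sampling
rate — the rate-based decoders of electrophysiology do not transfer.
`caldecode` instead reduces each neuron to a *binary* state per frame
(active during transient rises, inactive otherwise) and builds a fully
probabilistic pipeline on top of that reduction: tuning curves with
significance and confidence, a naive Bayes decoder of behavioral state,
and the reverse mapping from behavior to predicted activity.

## The probabilistic model

With binary activity $A_k$ of neuron $k$ and a discrete behavioral state
$S$ taking values $i = 1..M$ (3 cm track bins by default), everything is
estimated by counting frames over the *included* frames (immobility below
5 cm/s is excluded, because stationary activity can reflect internal
variables such as replay rather than position):

* marginal $P(A_k)$ — fraction of frames active ("bias"),
* prior $P(S_i)$ — occupancy,
* joint $P(S_i \cap A_k)$, and the tuning curve (likelihood)
  $P(A_k \mid S_i)$,
* posterior $P(S_i \mid A_k) = P(A_k \mid S_i) P(S_i) / P(A_k)$.

Because every term is a plug-in frequency from the same frames, each
posterior sums to exactly 1 — asserted at $10^{-12}$ in the tests. Mutual
information between the binarized activity and the state,
$\mathrm{MI}_k = \sum_{i}\sum_{j\in\{a,\bar a\}} P(S_i \cap A_j)
\log_2 \frac{P(S_i \cap A_j)}{P(S_i) P(A_j)}$,
ranks neurons by how informative they are; states never visited carry an
explicit `NA` ("undefined") rather than 0 — a 0 would claim certain
silence — and are skipped by MI, smoothing, and decoding.

The decoder assumes conditional independence across neurons and scores
each state by the active neurons' evidence,
$\prod_{k \in \text{active}} P(A_k|S)\,P(S)/P(A_k)$, computed in log
space. Two scoring variants are kept strictly separate because they do
not rank states identically:

* `log_product` (default): sums $\log P(A_k|S) + \log P(S) - \log P(A_k)$,
  with a zero likelihood treated as $-\infty$ — an active neuron that was
  never active in a state during training vetoes that state.
* `log1p`: sums $\log(1 + P(A_k|S) P(S)/P(A_k))$, an
  underflow-avoiding transform in which zeros contribute nothing instead
  of vetoing. The claim that this transform preserves the argmax of the
  product is not true in general — a sum of $\log(1+x_k)$ does not order
  like $\prod x_k$ — which is why both variants exist and are tested
  against a brute-force linear-space oracle where they do agree
  (strictly positive likelihoods).

Prior modes: `uniform` (flat $1/M$, the default, and empirically the best
choice for sparse sessions), `observed` (occupancy), and `unbiased`
($P(A_k) := 1$ with a flat prior). Under `log_product` scoring the
unbiased mode provably changes nothing — removing $\log P(A_k)$ shifts
every state's score by the same frame constant — and the test suite
asserts this; differences between biased and unbiased decoding can only
arise under the nonlinear `log1p` scoring.

## Binarization

A frame is active iff the low-pass-filtered, z-scored trace exceeds 2 SD
*and* its first difference is positive: transient rise periods carry the
bulk of the underlying spikes, so only rises are labeled. Design points:

* The low-pass filter is zero-phase with an order-4 Butterworth magnitude
  response, applied in the Fourier domain on a mirror-padded signal
  (cutoff 2 Hz by default). No phase delay, unit DC gain — hence
  binarization is exactly invariant to affine transforms $a x + b$,
  $a > 0$, of the raw trace, which the tests assert.
* z-scores use the whole-recording mean/SD (no sliding baseline). A
  consequence worth knowing: for very active cells the transients inflate
  the SD and the 2 SD criterion becomes conservative. This is inherent to
  the method, which published ground-truth comparisons report captures
  roughly half of all spikes.
* Zero-variance (dead) traces warn and return all-inactive rather than
  erroring, so dead ROIs do not abort batch runs.

Two comparison methods are provided: a plain z-score threshold (no
derivative criterion; its active set is a superset of the rise criterion
on the same unfiltered trace) and an adapter for externally deconvolved
activity (active iff the deconvolved value is positive).

## Significance and confidence

Circular permutations rotate a neuron's full-length activity vector by a
uniform shift in $1..T-1$ (the identity shift is excluded — it only
dilutes the null) *before* the inclusion mask is applied, preserving
transient structure while destroying the activity–behavior relationship;
each surrogate conserves the active-frame count exactly. Empirical
p-values count surrogates strictly above the actual value divided by the
number of permutations (they can be exactly 0); an inclusive mode is
available because strict counting overstates significance when surrogates
tie the actual value, e.g. in empty bins. No multiple-testing correction
is applied across bins by default, matching the per-bin thresholding
convention of place-field displays.

Bootstrap confidence bands resample included frames with replacement
(1000 samples of 50% of the frames by default) and take percentile
intervals per state. Note a calibration subtlety: resampling only half
the data widens the band, so the default band *over-covers* the
underlying per-state probability; coverage is nominal (93–97% observed
for 95% intervals in the acceptance suite) for the n-out-of-n bootstrap
(`sample_fraction = 1`), which is what the coverage test uses.

## Temporal filtering — a deliberate deviation

Pooling the log-scores of $L = \mathrm{round}(w \cdot \text{rate})$
adjacent frames (the product of temporally adjacent posteriors)
suppresses erratic jumps in the decoded trajectory. The literal
formulation uses only *past* frames. Implementing that literally
introduces a systematic lag: evidence is centered $L/2$ frames in the
past, displacing the decoded position by $v \cdot w/2$ — 5 cm at
20 cm/s for a 0.5 s window — which measurably *increases* decoding error,
the opposite of the filter's purpose (we verified the decoded trajectory
aligns best with the truth shifted 12–16 frames back). The package
therefore centers the window by default (`window_mode = "centered"`),
the same zero-phase choice made for the trace filter, and retains
`window_mode = "past"` for strictly causal/real-time semantics. Frames
with no active neuron anywhere in the window carry no evidence: they
receive the prior and are flagged undecodable rather than scored.

## The synthetic world

The generator emulates the recording conditions the pipeline targets so
every stage can be tested against known ground truth without downloads:

* 15 min sessions at 30 Hz; a 100 cm linear track traversed at
  ~20 cm/s with exponential immobility pauses at the reward ends, or a
  45×45 cm open field explored by a persistent random walk with
  reflecting walls (heading SD 0.25 rad/frame — smooth, curved paths that
  cover every 3 cm bin within a session).
* Gaussian place fields (SD 5 cm) tiling the arena with ±1 bin jitter;
  Bernoulli events per frame with peak rate `p_max = 0.1`/frame (3
  transient onsets/s at the field center — at the active end of realistic
  GCaMP6f transient rates; 9/s would merge into a continuous envelope)
  over a 0.01/frame baseline. A configurable fraction of cells is
  direction-selective (field rate only in the preferred running
  direction), emulating the unidirectionality of linear-track place
  fields.
* Double-exponential transients (rise 0.1 s, decay 1 s, conventional
  GCaMP6f values — the underlying study does not report its own
  kinetics), linear superposition, additive Gaussian noise at 1/10 of the
  transient amplitude.

What the generator does *not* emulate — and hence what a green test does
not establish: correlated noise and neuropil contamination, photobleaching
drift, indicator saturation and bursting nonlinearities, soft field
boundaries, theta-phase or sequence structure, and inter-neuron
correlations (the decoder's independence assumption is exactly true in
the synthetic world, unlike in real data).

## Numerical and policy choices

* Bins are half-open `[k·w, (k+1)·w)`; the far wall clamps into the last
  bin, which may be narrower (100 cm / 3 cm gives M = 34 with a 1 cm last
  bin); an equal-width mode is available.
* MAP ties break to the lowest state index, for determinism.
* Undefined-state handling: states unvisited in training are removed from
  the decodable space; tuning-curve noise injection only corrupts
  *defined* entries so that corruption cannot enlarge the state space.
* Gaussian tuning-curve smoothing uses a truncated (±4σ) kernel
  renormalized over defined bins (no wraparound — tracks are not
  circular); it is applied to the likelihood only and is primarily a
  robustness/ablation device, since smoothing measurably degrades
  decoding.
* Train/test splits are block-wise (5 s blocks by default — long enough
  to keep a transient inside one epoch) and never overlap; excluded
  frames belong to neither set. The epoch block length is not prescribed
  anywhere, so it is a configurable default.
* All randomness flows from explicit seeds through `withr::with_seed`;
  fixed seeds reproduce sessions, surrogates, bootstraps, splits, and
  posteriors bit-identically.
* Serialization is CSV + JSON only; no HDF5 binding is available in the
  supported toolchain.

## Known limitations

* The rise-criterion raster lags the underlying events by a few frames
  (the z-threshold is crossed partway up the transient), which blurs
  tuning curves by ~1 bin per running direction and sets a floor on
  calcium-pipeline decoding error that ground-truth event rasters do not
  have.
* Whole-recording z-scoring under-detects transients in very active
  cells.
* MI is bin-count sensitive; comparisons are only meaningful at matched
  discretization.
* The decoder has no transition model; a Markov/transition-matrix prior
  is a documented extension point, not an implemented feature.
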