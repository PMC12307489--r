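---
title: "HA-FuseNet: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HA-FuseNet: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Motor imagery (MI) — imagining a movement without executing it — modulates
sensorimotor EEG rhythms: mu (8–12 Hz) and beta (18–26 Hz) band power drops
over the contralateral motor cortex during imagery (event-related
desynchronization, ERD). Decoding which of four imagined movements (left
hand, right hand, feet, tongue) produced a 22-channel EEG trial is the
canonical four-class MI classification task. EEG makes this hard: the signal
is non-stationary, the signal-to-noise ratio is low, datasets are small
(tens of trials per class and subject), and spatial/spectral signatures vary
strongly across subjects.

`hafusenet` implements HA-FuseNet, an end-to-end classifier built from two
complementary branches whose features are fused along the depth (feature-map)
dimension:

* **DIS-Net**, a convolutional branch for local spatio-temporal structure:
  a temporal stem, an inverted bottleneck (1×1 expand → depthwise temporal
  convolution → 1×1 project), two multi-scale blocks whose parallel temporal
  kernels are sized to mu/beta cycle lengths and whose outputs are
  depth-concatenated with the block input (dense connectivity), an svSE
  hybrid attention stage after each block, and an axial depthwise-separable
  spatial convolution that collapses the electrode axis.
* **LS-Net**, a recurrent branch for global dependencies: stacked LSTM layers
  over the raw `C × T` epoch; after each layer the hidden-state sequence
  `Y ∈ R^{H×T}` passes through SCoT, a two-stage global attention (Non-local
  self-attention over channel tokens, then contextual-transformer-style
  temporal attention), with H treated as the channel axis.

The R2C adapter projects the LS-Net sequence back to map form per time step;
it is depth-concatenated with the DIS-Net feature map, and a depthwise
separable convolution, pooling, flattening and a fully connected Softmax
head produce the four class probabilities. Training uses categorical
cross-entropy and Adam (learning rate 1e-3, weight decay 5e-3, batch size
32); the reference schedule is 300 epochs.

## The attention modules

**svSE.** For a feature tensor `X ∈ R^{D×C×T}` three weight maps are
computed. The channel branch squeezes each depth map with a *global max* over
`(C, T)` (max rather than average, to favor salient features), passes the
D-vector through a reduce–expand excitation (reduction ratio `r = 2`, GELU)
and normalizes with a Softmax over depth. The variance branch stacks the
depth-wise mean and population variance at each `(c, t)` position — variance
carries exactly the band-power information that distinguishes ERD states —
fuses them with a 1×1 convolution and normalizes over the `C×T` positions.
The axial branch computes a channel factor (time-axis average and max
pooling of a depth-compressed map, fused 1×1) and a time factor (a `C×1`
convolution spanning the electrode axis), and recombines them by Kronecker
product. The output is
`X_svSE = (Att_v ⊕ Att_s) ⊗ X ⊕ Att_c ⊗ X`.

Two normalization choices were genuinely open and we fixed them as follows:

* *Softmax placement in the axial branch.* The weight map is required to be
  both Softmax-normalized and rank-1. A Softmax applied **after** the outer
  product destroys rank-1 (the exponential of a rank-1 matrix is not
  separable), so each factor is normalized on its own axis first; the outer
  product of two probability vectors is rank-1 **and** sums to 1 over the
  `C×T` positions, satisfying both properties at once.
* *Residual copy.* Softmax-normalized maps sum to 1 over ~`C·T` positions,
  so the multiplicative paths scale activations by roughly `1/(C·T) + 1/D`
  per stage; three stacked svSE stages attenuate the forward signal by three
  orders of magnitude, and in our experiments the desk-scale network then
  barely trains (≈43% training accuracy after 15 epochs of the benchmark
  below). With a residual copy of the input added to the gated output the
  same benchmark reaches 100% held-out accuracy. The network default is
  therefore `svse_residual = TRUE`; `svse_apply()` exposes the bare
  equation form (`residual = FALSE`) for verification.

**SCoT.** `SCoT(X) = Att_st(Att_s(X))`. The spatial stage adapts the
Non-local block: each channel position becomes a token described by its
depth vector after mean-pooling over time (keeping the similarity matrix a
cheap, well-conditioned `C×C`; a time-resolved token mode is available by
configuration), query/key/value come from three 1×1 convolutions at half
depth (`⌈D/2⌉`, floor 1), the similarity matrix is Softmax-normalized
row-wise, and the re-expanded output is added residually. The temporal stage
follows the contextual-transformer pattern mapped from 2-D images to the
time axis: a depthwise 1×3 convolution provides the static-context key, the
value is a 1×1 convolution, the attention map comes from two chained 1×1
convolutions (GELU between) on the depth-concatenation of key and query, the
dynamic context is the element-wise product with the value summed over the
local kernel footprint, and static and dynamic contexts are fused by
addition. Splitting attention into a `C×C` stage plus a local temporal stage
costs orders of magnitude fewer multiply–accumulates than one joint
`(C·T)×(C·T)` attention (`attention_macs()` gives the closed forms).

**SG.** The separable-ghost convolution replaces a standard temporal
convolution: `round(d_out · ratio)` maps come from a standard convolution
and the remaining maps are generated from them by a cheap depthwise 1×k →
batch-norm → 1×1 pointwise → batch-norm → GELU path, all depth-concatenated
so the output width is exactly `d_out`. Fractional map counts are rounded
with a floor of 1 per path; `ratio = 1` degenerates to the standard
convolution. At the default geometry the SG variant of the full network has
strictly fewer parameters at the same interface.

## Preprocessing

GDF recordings are reduced to EEG channels (EOG excluded by label), gaps
(NaN runs between recording blocks) are filled by channel-wise mean
imputation, and one epoch per motor-imagery cue is cut over the half-open
window `[cue + 1 s, cue + 4 s)` — 1 s after the cue because ERD builds up
with a short latency and the early segment is contaminated by visual evoked
activity; at 250 Hz every epoch is exactly 750 samples. Evaluation-session
labels come from the accompanying MAT file. Epochs are z-scored
(`(x − μ)/σ`, population σ, ε = 1e-8 degeneracy guard) per trial and channel
over the time axis — the self-contained choice under non-stationarity, which
also cannot leak test-set statistics; per-channel-over-session scope and
min–max normalization (`(x − min)/(max − min)` onto [0, 1]) are available by
argument. Whether evaluation sessions should reuse training-session
statistics is not prescribed anywhere we could find; the self-contained
per-trial default sidesteps the question and the scope argument leaves the
alternative open. No band-pass filtering is applied at any point, keeping
broad-band information intact.

## The synthetic study

Real four-class recordings cannot be redistributed with the package, so a
generator emulates their decision-relevant structure: 22 channels at 250 Hz,
1/f-shaped background noise (`noise_sd = 2` µV), and narrowband mu rhythms
(10 Hz, ~1 Hz linewidth, 8 µV) on four disjoint channel pairs placed at the
motor-strip rows of the standard montage (left hand → right-hemisphere pair,
right hand → left-hemisphere pair, feet → midline, tongue → a posterior
pair). During a trial of the matching class the rhythm amplitude is
multiplied by the attenuation factor (default 0.3) from 0.5 s to 4 s after
the cue with 0.5 s linear ramps — an ERD analogue. Per-subject variability
is a log-normal channel gain (sd 0.1). Trials are 6 s cycles with 2 s
lead-in; cue events carry the standard four cue codes; everything is
deterministic given (seed, subject, session).

What this generator does **not** emulate: volume-conducted scalp
topographies (class signatures here live on disjoint channels, which is far
cleaner than reality), ocular/muscular artifacts, inter-session drift, beta
rhythms and cross-frequency structure, and realistic inter-subject
variability beyond channel gains. Passing the learning checks therefore
demonstrates that the architecture, gradients, optimizer and protocols work
end to end — not that the model attains any particular accuracy on real
recordings.

## Scale, runtimes and the desk benchmark

The numerical core is written for one CPU: reverse-mode automatic
differentiation over dense arrays with compiled kernels (BLAS-backed
temporal convolutions, a fused LSTM with hand-written backpropagation
through time, broadcast/reduction primitives). The `"full"`-scale
configuration reproduces the reference geometry (1×25 stem at 250 Hz = 100
ms, branch kernels 15–65 samples, H = 64). The `"desk"` scale — used by the
test-suite and `scripts/acceptance.R` — decimates epochs by 10 (75 samples
at an effective 25 Hz; a boxcar average keeps ≈76% of 10 Hz mu amplitude, so
the band-power contrast survives), scales kernels to the same milliseconds
(3–9 samples = 120–360 ms), and uses stem depth 6, branch depth 4,
expansion 2, spatial depth 24, H = 40 and a 64-unit hidden classifier layer:
about 4.9 × 10⁴ trainable parameters, ≈0.6 s per 32-trial training
iteration.

The standard benchmark (`synthetic_benchmark()`) generates 9 subjects × 80
trials, holds out 12 trials per class and subject (288 train / 432 test),
and trains the desk model for 40 epochs at batch 32 (≈3.5 minutes). On
separable data (attenuation 0.3) it reaches ≥90% held-out accuracy (100% at
seed 1); on signal-free data (attenuation 1.0) accuracy stays inside the
binomial band around the 25% chance level. The model-family comparison
(fusion versus the convolutional-only ablation, SG versus standard) runs at
a reduced size — 4 subjects, attenuation 0.2, 16 epochs — where all three
variants converge in a couple of minutes each; at that scale the relative
statements (within five accuracy points, fewer parameters) are stable while
absolute accuracies would not be. The protocol tests run the
within-subject and leave-one-subject-out machinery at miniature scale (a
few hundred parameters, 1–3 epochs), since what they verify is set
assembly, not accuracy.

## Numerical choices

* Population (divide-by-n) variance everywhere a plain z-score or variance
  map is meant; sample variance (n−1) only in the across-subject SD of
  accuracies, which is an estimator over subjects.
* Zero-probability guard `ε = 1e-12` inside cross-entropy; normalization
  degeneracy guard `ε = 1e-8` (constant groups map to zeros).
* Max-pooling ties break to the first index, making forwards and gradients
  reproducible.
* Weight decay is classic L2 added to the gradient, applied to weights but
  not biases or norm affines.
* One master seed fans out (deterministic integer mixing, 32-bit safe) to
  initialization, minibatch order, dropout and the generator; identical
  seeds give bit-identical histories.
* Temporal alignment before fusion average-pools the longer map by an
  integer factor; both branches preserve T in this architecture, so the path
  is normally inactive.
* GELU is exact (`x·Φ(x)`), not the tanh approximation.

## Known limitations

* The exact wiring of the bidirectional C2R/R2C interaction is the largest
  documented interpretation in the package: C2R optionally feeds the
  post-stem DIS feature map into LS-Net (`lsnet_input = "c2r"`; raw epochs
  are the default input), and R2C returns the LS-Net sequence for
  depth-concatenation before the fused head. The adapters themselves are
  per-time-step linear projections.
* svSE insertion points follow the "after temporal blocks and after the
  spatial convolution" reading; alternatives are untested.
* Batch statistics are only used inside SG batch-norms; the standard variant
  carries no normalization layers.
* Training runs a fixed epoch count (no early stopping); `val_fraction`
  exists for monitoring only.
* The `"full"`-scale configuration is provided and runs, but nothing in the
  package (or its tests) certifies benchmark-dataset accuracies; those
  require the external recordings and GPU-scale training.
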