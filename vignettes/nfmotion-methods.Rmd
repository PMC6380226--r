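---
title: "Modeling motion selectivity with asymmetric Hebbian neural fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling motion selectivity with asymmetric Hebbian neural fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nfmotion)
```

## The model

`nfmotion` simulates sheets of rate neurons — *neural fields* — stacked
into a feed-forward hierarchy that mirrors the early dorsal visual stream:
an input layer (retina), a first field resembling V1, and optionally a
second field resembling MT. Each neuron has

* an **afferent receptive field**: a square patch of the layer below,
  connected through nonnegative weights;
* **short-range lateral excitation** to neurons within a radius
  `r_exc` of itself on the sheet, and
* **long-range lateral inhibition** from the annulus
  `r_exc < d <= r_inhb` (Euclidean distance by default, Chebyshev
  optionally).

For every stimulus frame the neuron first computes its afferent drive,
the scaled inner product of its weight patch with the input inside its
receptive field, squashed by a piecewise-linear sigmoid:

$$S_{ij} = \sigma\!\left(\gamma_{\text{aff}}\; \mathbf{W}_{ij}\cdot
\mathbf{X}_{ij}\right)$$

and then iterates the lateral dynamics for `Ts` *settling* steps at fixed
afferent drive:

$$\eta_{ij}(s) = \sigma\!\Big(S_{ij}
 + \gamma_{\text{exc}} \textstyle\sum_{kl} \eta_{kl}(s-1) E_{ij,kl}
 - \gamma_{\text{inhb}} \textstyle\sum_{kl} \eta_{kl}(s-1) I_{ij,kl}\Big).$$

Two timescales coexist: frames advance at the slow stimulus timescale
`t`, lateral settling at the fast timescale `s`. Activity is reset to
zero **between sequences only**; within a sequence the settling of frame
`t` starts from the settled state of frame `t-1`. This carry-over is
essential, not cosmetic: with frozen weights a field whose response is
recomputed from scratch every frame responds identically to a sequence
and to its time reversal, so nothing downstream could ever distinguish
leftward from rightward motion. Direction information lives in the
interaction between the carried activity state and the direction-biased
lateral circuitry.

## Learning

After settling on each frame, the *trainable* field (training is
layer-wise, one field at a time) updates its weights:

* **Afferent** (Hebbian): $\Delta W_{ij,kl} = \alpha_{\text{aff}}
  X_{kl}\,\eta_{ij}(t)$.
* **Lateral, asymmetric** (the model's core): $\Delta W_{ij,kl} =
  \alpha \max\!\big(0,\eta_{ij}(t)-\eta_{ij}(t-1)\big)\,
  \eta_{kl}(t-1)$ — presynaptic activity at the *previous* frame paired
  with the rectified *increase* of postsynaptic activity at the current
  frame, a rate-based analogue of spike-timing-dependent plasticity.
  Connections pointing "forward along the motion trajectory" are
  potentiated; the reverse connections are not. A temporally
  **symmetric** control rule ($\Delta W = \alpha\,\eta_{ij}(t)\,
  \eta_{kl}(t)$) is available to show that this asymmetry, not lateral
  plasticity per se, produces direction selectivity.
* **Divisive normalization**: after each update, every neuron's incoming
  weights of each type (afferent, excitatory, inhibitory, separately)
  are rescaled to unit sum. This bounds growth and makes learning
  competitive: weight gained on co-active inputs is weight lost
  elsewhere.

Weights are uniform random at initialization (then normalized to unit
sum per type); lateral weights are stored directionally —
`W[i→j]` and `W[j→i]` are independent entries, which is the point of the
model.

## The sigmoid thresholds, and why they matter

The activation function is piecewise linear: 0 below `sigma_lo`, 1 above
`sigma_hi`, linear between. The published parameter tables specify the
lateral gains but not these thresholds, and the choice is not free: with
unit-sum lateral weights, a spatially uniform activity profile grows per
settling step by the factor
$(\gamma_{\text{exc}}-\gamma_{\text{inhb}})/(\sigma_{hi}-\sigma_{lo})$.
With the naive identity sigmoid (`lo = 0, hi = 1`) every preset with
$\gamma_{\text{exc}} > \gamma_{\text{inhb}}$ drives the whole sheet to
the ceiling within a few settling steps; activity is then uniform at 1,
the asymmetric rule (which needs activity *increments*) sees nothing,
and no topography can form.

The presets therefore set each field's sigmoid span just above the
uniform-mode critical point,

$$\sigma_{hi}-\sigma_{lo} = \max\!\big(1,\;
\gamma_{\text{exc}}-\gamma_{\text{inhb}} + \delta\big),
\qquad \delta = 0.05.$$

The uniform mode then decays slowly while *localized* activity clusters
— which concentrate the excitatory disc's weight but spread little mass
into the inhibitory annulus — remain self-sustaining over the 10-step
settling window. The result is the classical centre-surround regime:
focused activity bubbles that persist and drift with the stimulus,
carrying the short-term memory of where the stimulus just was, and
multistable enough that a sequence and its time reversal settle into
different response profiles. On the bar preset this margin moves the
correlation between opposite-direction response vectors from ≈ 1 (wide
spans) to ≈ 0–0.3. Fields with net-inhibitory gains
($\gamma_{\text{exc}} < \gamma_{\text{inhb}}$, the random-dot NF1) are
unconditionally stable and keep the unit span.

One field resists this treatment: the random-dot NF2 has
$\gamma_{\text{exc}} : \gamma_{\text{inhb}} = 15.68 : 1$. With unit-sum
weights no *shared* sigmoid span works there — below span 14.68 the
uniform mode explodes, above it the afferent drive (at most $1/\text{span}
\approx 0.07$) decouples from the lateral terms, and because inhibition
is so weak relative to excitation, no finite-wavelength (Mexican-hat)
instability exists at any span: the uniform mode always has the largest
linear gain. The preset therefore gives this field *two* threshold
pairs: the afferent response keeps the unit-range sigmoid (so stimulus
evidence arrives at full scale) while the settling sigmoid spans
$[0, 15.18]$ (near-critical, margin $0.5$). This keeps the field
input-coupled and stable; its consequences for decodability are
discussed under limitations. The margins are fixed once in the presets;
they select a dynamical regime (bubble-forming rather than uniformly
saturating) and were not fitted to any benchmark quantity.

## Stimuli

All inputs are synthetic, generated by seeded code:

* **Bars**: 30 x 2 px white bar on a 64 x 64 black background, oriented
  perpendicular to its motion, 8 directions (45° apart), 8 frames,
  7.8 px/frame, trajectory centred on the frame. Positions accumulate in
  floating point and each frame is rasterized by testing pixel centres
  against the rotated rectangle (half-open bounds keep a width-2 bar
  exactly 2 px wide); no anti-aliasing.
* **Edges**: a half-plane of 1s advancing 1 px/frame over 64 frames, in
  the four cardinal sweeps; probes for component motion.
* **Gratings**: drifting sinusoids, spatial period 5 px, 10 frames,
  1 px/frame. The temporal phase is centred on the middle frame and the
  profile is a cosine, which makes the sequences for direction `d` and
  `d + 180°` exact time-reversals of each other — a property the test
  suite exploits.
* **Plaids**: the arithmetic mean of two component gratings at the
  pattern direction ±45°. Both components are in [0, 1], so the mean is
  too and superposing a grating with itself reproduces it exactly.
* **Squares**: a 24 x 24 px square translating through the frame centre,
  5 frames, 8 px/frame (rounded per axis for diagonals).
* **Random-dot fields**: 16 2 x 2 px dots on a 32 x 32 torus, one dot
  placed uniformly inside each 8 x 8 block of a fixed disjoint tiling;
  translated coherently 1 px/frame in the four cardinal directions with
  wrap-around, so dot density is conserved. 25 seeded configurations x 4
  directions = 100 sequences, split 80/20 into train/test *by
  configuration*, so held-out sequences have dot layouts the network has
  never seen.
* **Perturbations**: salt-and-pepper noise replaces a fraction `density`
  of pixels with fair coin flips in {0, 1} (on binary stimuli roughly
  half the replacements change the pixel, so density 0.02 visibly
  corrupts about 40 of 64 x 64 pixels); Gaussian noise adds zero-mean
  noise of a given variance and clips to [0, 1]; bar-length variants
  probe lengths 15–35 px.

What the generators deliberately do **not** emulate: luminance gradients
or contrast variation, anti-aliased or sub-pixel rendering, natural
image statistics, occlusion, or radial/rotational flow. A passing test
suite therefore says the model self-organizes under clean, binary,
single-object motion; it says nothing about natural movies.

## Geometry

A sheet's side length follows the sliding-window formula
`dim = (input - rf)/stride + 1` (`derive_dim()`). Several published
sheet sizes admit no integer stride (64-wide image, rf 24, dim 20; rf
12, dim 13; rf 64, dim 20); the published dims win and the receptive
field origins are spread as evenly as possible
(`round(seq(0, input - rf, length.out = dim))`). `rf == input` means
every neuron sees the whole input. The random-dot hierarchy is exact
with stride 1 on 32 x 32 frames: (32-4)/1+1 = 29 and (29-8)/1+1 = 22;
the parameter table's "image size 16 x 16" entry for that column
conflicts with the stimulus construction on 32 x 32 grids and is treated
as a bookkeeping inconsistency.

## Training protocol

One *epoch* presents the entire training set once, sequences drawn in
seeded random order. Layer-wise: a lower field is trained (up to its
epoch cap or until *saturation*: at least 80% of its trainable weight
entries changed by less than `1e-4` times the mean weight magnitude of
their type over the last epoch) and then frozen before the next field
trains. The random-dot protocol fixes NF1's afferent weights at 1
(`freeze_afferent`), so NF1 activity is position-homogeneous and only
its lateral circuitry adapts.

## Maps, robustness, decoding

* `preferred_directions()` probes a frozen network with one sequence per
  direction; a neuron's response to a sequence is its maximum settled
  activity over the frames, its preferred direction the probe evoking
  the largest response (ties to the lowest angle, deterministically).
* `robustness_index()` is 1 minus the fraction of neurons whose
  preferred direction changes under a perturbation; `run_noise_sweep()`
  (probe-time noise, no retraining), `run_noise_training_trials()`
  (retraining under noise, convergence = saturation + full direction
  coverage) and `run_bar_length_sweep()` build the robustness analyses.
* `new_perceptron()` / `train_perceptron()` implement the single-layer
  logistic readout trained by the online delta rule (α = 0.1, one-hot
  targets, per-class biases, seeded shuffles); it is a probe of
  decodability, not part of the modeled pathway. The feature vector for
  a sequence is the final frame's settled activity of the source field
  (the flow response is nearly stabilized by then); mean-over-frames is
  available as an alternative.

## Numerical choices

* Weight updates run in place in C++ (allocating a fresh multi-MB matrix
  per frame costs more than the arithmetic); fields are therefore
  environments with reference semantics, and `clone_field()` /
  `clone_network()` take independent snapshots. Pure-R loop
  implementations of every equation live in the test suite and the
  vectorized paths are required to match them to 1e-10 on small fields.
* Divisive normalization with an all-zero denominator (a dead neuron)
  leaves the weights unchanged.
* All randomness (weight init, presentation order, dot placement, noise,
  decoder shuffles) is derived from user-supplied seeds; identical seeds
  give bit-identical runs.

## Problem sizes used by the tests and the acceptance script

The shipped presets carry the published epoch caps (200–1500). The test
suite and the acceptance script run the same network sizes but smaller
epoch budgets — enough for the self-organization to express itself while
keeping a full multi-seed replication within minutes on one CPU:
150 epochs for asymmetric bar runs (60 for the symmetric control, whose
verdicts are already stable there), 120 for the noisy-retraining
trials, 8 + 8 field epochs for the random-dot hierarchy in the tests
and 20 + 12 in the acceptance script. Saturation stopping applies in
all cases (in practice the bubble-forming regime keeps adapting and
runs to its cap; heavily noise-corrupted runs freeze early). Training
longer sharpens the maps but does not change their qualitative
structure; exact eight-direction map coverage remains a stochastic
event from seed to seed at any budget we ran.

## Known limitations

* The sigmoid-threshold rule above is this package's resolution of an
  under-determined part of the published model; other resolutions
  (adaptive thresholds, unnormalized lateral weights) could behave
  differently.
* Decoding translational flow through NF2 underperforms decoding NF1
  directly. The direction signal the asymmetric rule writes into NF1 is
  real — a linear readout of NF1's settled activity classifies all
  training sequences and well above chance on held-out dot
  configurations — but NF2's extreme excitation-to-inhibition ratio
  forces the near-critical settling regime described above, whose strong
  amplification concentrates response variance in a few spatial modes.
  The resulting NF2 features are ill-conditioned for the 300-epoch
  delta-rule perceptron, and accuracy through NF2 drops to roughly half,
  rather than improving on, the NF1 readout. We found no configuration
  of the unspecified sigmoid thresholds under which this field both
  stays stable and integrates the flow signal; the acceptance report
  states the measured accuracies as they are.
* Map topography is sensitive to the lateral radii and gains, as the
  original parameter exploration notes; the presets are fixed points of
  that exploration, not robust defaults for arbitrary stimuli.
* No feedback (top-down) connections, no spiking dynamics, no
  radial/rotational flow; the perceptron is linear and single-layer by
  design.
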