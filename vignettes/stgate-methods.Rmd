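---
title: "Spatial-temporal graph attention for EEG emotion classification: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-temporal graph attention for EEG emotion classification: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, the synthetic data it is validated on, and the
numerical and design choices that were genuinely open.

## The classification problem

Cross-subject EEG emotion recognition asks whether a model trained on some
subjects' recordings can classify the emotional state of an unseen subject.
Each trial is a multichannel recording (channels × samples, microvolts, at a
fixed sampling rate). The standard pipeline reduces it to per-window,
per-band features and classifies sequences of windows. Evaluation is
leave-one-subject-out (LOSO): one fold per subject, trained on all other
subjects, so no information about the test subject — including
normalization statistics, which this package fits on the training fold only
— is available at training time.

## Features

Signals are decomposed into the five canonical bands — delta (1–3 Hz),
theta (4–7 Hz), alpha (8–13 Hz), beta (14–30 Hz), gamma (>31 Hz) — with
order-4 Butterworth band-passes applied forward-backward (zero phase), so
band energy is not time-shifted between bands. The open-ended gamma edge is
capped at 0.45 × the sampling rate. Per 1-second window (non-overlapping by
default; both length and stride are configurable) the package computes:

* **DE** (default): differential entropy under a Gaussian model,
  `0.5·ln(2πeσ²)` of the band-filtered window. The variance is floored at
  1e-12 before the logarithm so constant windows stay finite. The Gaussian
  closed form, rather than a histogram estimator, is the standard
  construction for band-filtered EEG and is deterministic; its scale rule
  `DE(aX) = DE(X) + ln a` is exact and tested.
* **PSD**: mean periodogram power over the band's frequency bins, reported
  on a natural-log scale with an epsilon guard.
* **DASM / RASM / ASM**: left minus right, left over right
  (epsilon-guarded), and their concatenation, computed from DE over
  symmetric electrode pairs. ASM has no single established definition; the
  concatenation convention is used here and stated openly.

Optional moving-average smoothing along the window axis is off by default:
whether temporal smoothing was applied to DE features in the reference
protocol is not stated, and leaving it off keeps the feature a pure
per-window quantity.

## The network

Samples are sequences of `T = 10` consecutive windows, shaped
channels × bands × windows (N × 5 × 10). The variant grid wires four
components:

1. **Convolution stack** (all variants). Each electrode's 5 × 10
   band-time plane is convolved with shared weights: 3×3 → ReLU → 3×3 →
   ReLU → 1×1, unpadded, so the band axis collapses 5 → 3 → 1 and the time
   axis shortens to `T_r = T − 4 = 6`. Treating electrodes as batch
   entries (not a convolution axis) keeps the block electrode-level and
   permutation-equivariant, which the test suite asserts. The kernel order
   (two 3×3 then a 1×1) follows the published description of the stack;
   the width is C = 32 channels.
2. **Transformer encoder** (TLB variants). Each electrode's `T_r` tokens
   of width C receive a learned positional embedding and pass through 2
   pre-norm encoder layers (4 heads, feed-forward width 2C). Depth 0
   degenerates to the positional embedding alone, which makes the wiring
   testable in isolation.
3. **Spatial and temporal attention** (graph variants).
   Spatial: `S = V·tanh(W1·X·W2 + b_s)` with `W1 ∈ R^{T_r}` contracting
   time, `W2 ∈ R^{C×N}` projecting channels to nodes, and `V, b_s ∈
   R^{N×N}`; scores are standardized with mini-batch mean and *population*
   variance (the batch-normalization convention, with a learnable affine
   and running statistics for inference) and every row keeps only its
   k = 10 largest entries (ties broken toward the lower column index,
   stable and tested). Temporal attention mirrors the construction on the
   time-transposed tensor — the published parameter shapes for the
   temporal map are inconsistent with a `T_r × T_r` output, so the mirror
   construction (`U3 ∈ R^N`, `U4 ∈ R^{C×T_r}`) is used and documented
   rather than silently patched. The temporal map re-weights the encoded
   sequence, `X̂[b,n,c,·] = T̂[b]·X[b,n,c,·]`.
4. **Graph attention classifier** (graph variants). One GAT layer over
   node features (the flattened C·T_r encoding) with K = 4 heads of width
   32: attention logits `LeakyReLU(a⃗ᵀ[Wh_i ‖ Wh_j])` (slope 0.2),
   softmax over the neighbourhood — the nonzero entries of the node's
   adjacency row plus a mandatory self-loop — and head outputs averaged,
   then an ELU. For the dynamic adjacency the retained Top-K edge weight
   multiplies the message (`α_ij·A_ij·Wh_j`; self-loops weigh 1 unless
   Top-K kept the diagonal). This multiplicative coupling is the package's
   resolution of a genuine gap: with a purely structural (mask-only) use
   of A, no gradient reaches the spatial-attention parameters at all,
   contradicting the premise that the adjacency is learned during
   training. On a binary static graph the weighting is the constant 1 and
   the layer reduces to a plain GAT, which is what the `tgat` variants use
   over a k-nearest-neighbour graph (k = 10) built from 2-D electrode
   positions. Readout is mean over nodes → dropout → linear; loss is
   cross-entropy. Neither readout nor loss is prescribed by the reference
   description; these are the simplest standard choices.

The eight ablation variants (`baseline`, `tlb`, `sgat`, `tgat`,
`sgat_tlb`, `tgat_tlb`, `stgat`, `stgate`) share initialization code, and
the full model's parameter set is a strict superset of every ablated
variant's, so ablations differ only by the wiring under test.

## Training

Adam (β₁ = 0.9, β₂ = 0.999), cross-entropy, and the reference stopping
rule: training ends when the epoch-mean training loss drops below 0.15. A
`max_epochs` guard (default 200) covers data on which the threshold never
triggers. The defaults (learning rate 1e-5, batch 16, dropout 0.3) are the
published protocol; `train_config_test()` is a desk-scale profile
(learning rate 1e-3, batch 32, 40 epochs) used by the test suite and
example experiments. Everything is seeded: initialization, shuffling and
dropout derive from the training seed, and LOSO fold f trains with
`seed + f`, making per-subject accuracies bit-reproducible.

All forward and backward passes are hand-derived and implemented in
vectorized base R over column-major arrays, with three compiled kernels
(batched matrix product, im2col convolution, zero-phase IIR filtering)
where profiling showed R-level overhead dominating. Every layer's gradient
is validated against central finite differences (step 1e-5) across the
variant grid, and each attention operation against an independent
naive-loop oracle at tolerance 1e-5.

## The synthetic cohort

The generator emulates the *structure* of multi-subject emotion corpora
without reproducing any real data: 8 subjects × 3 classes × 6 trials of
20 s at 200 Hz over 24 channels on a ring montage with mirrored
left/right labels. Class identity is carried by inter-channel coupling:
each class owns 10 uniformly sampled channel pairs, and each coupled pair
shares a band-limited latent oscillator (alpha, beta or gamma — the bands
most associated with emotional state in the EEG literature; delta/theta
carry no class signal) injected into both endpoints with amplitude 0.8
on top of 1/f background noise. Subjects differ by a log-normal
per-channel gain (sd 0.2) and additive white noise (sd 0.5), values chosen
once as a realistic degree of inter-subject variability that keeps LOSO
nontrivial but solvable. Coupled pairs therefore show elevated band-limited
correlation (tested, and monotone in the coupling strength at 0, 0.4,
0.8), and endpoint channels carry class-dependent band power that DE
features expose.

What the generator does **not** emulate: volume conduction and reference
effects (which correlate *all* real channels), artifacts (ocular, muscle),
non-stationarity within trials, and realistic electrode geometry. Passing
tests on this cohort therefore demonstrate that the implementation learns
class structure from band-limited, graph-coupled signals under subject
shift — not that the architecture reaches any particular accuracy on real
EEG corpora.

Experiments in the tests and the acceptance script use this default cohort
(288 model samples), three generator/training seeds, and the desk-scale
training profile; these sizes are the package's chosen desk-scale
experiment.

## Known limitations

* **Averaged-adjacency interpretability.** The learned dynamic adjacency,
  averaged over samples and symmetrized (with the ten globally strongest
  edges exported, following the published visualization procedure), should
  be read as a map of *jointly informative* channels, not as a
  connectivity estimate. Two structural facts limit pair-level recovery of
  the generator's ground-truth coupling: the spatial-attention score
  contracts the time axis before any cross-channel product, so it cannot
  measure within-sample co-fluctuation — the signal that actually
  identifies coupled pairs (a direct window-level correlation of DE
  features recovers the ground-truth union perfectly); and the
  mean-over-nodes readout of a single graph-attention layer makes the loss
  nearly invariant to redistributing edge weight within an adjacency
  column, so training pressure selects important *columns* (channels)
  rather than specific pairs. Both averaging modes (pre-Top-K standardized
  scores, the default, and post-Top-K) are implemented; the default avoids
  biasing toward frequently selected but weak edges.
* The temporal-attention parameter shapes are a documented reconstruction
  (see above), as is the ASM definition.
* Batch-normalization running statistics make inference-mode adjacencies
  depend (deterministically) on training history; evaluation-mode forward
  passes are bitwise repeatable, which the suite asserts.
* The EDF reader covers continuous uniform-rate recordings (the common
  case for emotion corpora), not discontinuous EDF+D files.
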