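---
title: "Methods: a two-phase multitask pipeline for pulmonary embolism detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-phase multitask pipeline for pulmonary embolism detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem and model overview

Pulmonary embolism (PE) is diagnosed on CT pulmonary angiography (CTPA), a
3D modality read slice by slice. peflow implements a two-phase pipeline
that predicts, for each study, (i) the presence of PE per 10-slice 3D
window and (ii) nine study-level attributes: negative for PE,
indeterminate, chronic, acute-and-chronic, central/left/right PE, and
RV/LV diameter ratio at least 1 or below 1.

**Phase 1** is a 3D convolutional backbone classifying individual windows.
Its 512-d penultimate activation is exported as the window feature.
**Phase 2** treats the ordered window features of a study as a sequence:
each position is augmented with its differences to both neighbors
(512 × 3 = 1536-d), the sequence is canonicalized to length 40, a dilated
causal temporal convolutional network (TCN) maps it to 40 × 128
embeddings, a shared linear head predicts per-window PE logits, and nine
label-specific attention heads pool the embeddings into per-study logits
through two-layer MLPs.

## Preprocessing

Raw CT pixels are converted to Hounsfield units by the affine rescale
`HU = raw × slope + intercept`, with slices ordered bottom-to-top by
z-position (ties broken by instance number). Volumes are resampled to
1 mm isotropic spacing by per-axis linear interpolation; the output extent
per axis is the physical extent rounded to whole millimetres. Slice
labels are resampled by an interval-overlap rule: an output slice is
positive when its source interval overlaps any positive input slice.
This is deliberately conservative — resampling can widen a positive
region by a slice but can never delete one.

Lung localization uses a pluggable per-slice segmenter; the default
thresholds at −320 HU, removes connected components touching the slice
border, and applies a binary closing. The masks feed only a 3D bounding
box, so the demands on the segmenter are modest; an empty segmentation is
an error that callers (and `preprocess_study()`) resolve by falling back
to the full volume.

The cropped volume is split into consecutive, non-overlapping 10-slice
windows. A terminal partial window is padded by replicating its last real
slice — dropping it would discard apex or base pathology — and its label
comes from real slices only. Each window's label is the OR of its member
slice labels. Windows are rendered into three channels through the
standard lung (L = −600, W = 1500), PE (100, 700) and mediastinal
(40, 400) display windows: channel values are
`(clip(HU, L−W/2, L+W/2) − (L−W/2)) / W`, which saturate exactly at the
clip bounds (−1350, 150), (−250, 450) and (−160, 240) and lie in [0, 1].

## Phase 1: the 3D backbone

The backbone sits behind a fixed contract — any `(H, W, 10, 3)` window in
[0, 1] maps to a 512-d penultimate feature and a scalar PE logit — so the
architecture is a configuration choice, not a code path. The default
configuration mirrors the 3D ResNet-18 stage layout (stem + four stages of
two residual blocks, channels 64/128/256/512); the test profile used in
CI shrinks this to two stages of one block (channels 8/16) and 32 px
crops so the identical code path trains on a CPU in seconds. Blocks are
plain residual convolutions with He initialization and no batch
normalization; at desk scale normalization layers added nothing but
bookkeeping, and the contract keeps a normalized backbone swappable.
Pretrained video weights are intentionally out of scope; random
initialization is the supported path.

Training augmentation resizes slices to 224 px, applies one random
in-plane rotation of up to 15° (a single angle shared by all 10 slices of
a window — per-slice angles would shear anatomy across the z axis) and a
random crop to 192 px; evaluation resizes directly to 192 px. The loss is
mean binary cross-entropy with logits; optimization is Adam
(learning rate 4 × 10⁻⁴, batch 16, 20 epochs at full scale) and the
checkpoint with the maximum validation AUROC is kept, earliest epoch on
ties.

All forward/backward passes are hand-written matrix computations
(im2col + BLAS); the test suite pins them to finite-difference gradients
at tolerance 10⁻⁴ or better.

## Phase 2: sequence canonicalization, TCN, attention

`assemble_sequence()` computes neighbor differences on the raw windows
first (replicate-edge neighbors, so the terminal difference blocks are
exactly zero) and then canonicalizes the length: sequences shorter than
40 are zero-padded at the end behind a validity mask; longer sequences
are resized to 40 by per-column linear interpolation. Interpolation was
chosen over subsampling because it uses every source window; window
labels are reduced onto the canonical grid by an OR over an equal 40-way
partition of the source windows so a positive window can never be lost,
at the price of occasionally widening a positive by one grid cell. The
number of window loss terms for a study is therefore `min(N, 40)`, and
the batch loss denominator `sum(N_i + 9)` uses that count, matching the
one-study example `N = 3 → denominator 12`.

The TCN stacks two residual levels (zero-based level *i* has dilation
`2^i`, so 1 and 2); each level holds two dilated convolutions (kernel 3,
128 output channels), each followed by weight normalization, ReLU and
dropout 0.2, plus a residual connection using a 1 × 1 convolution when
channel counts differ. Convolutions pad `(k − 1)·d` causally — the
implementation left-pads and keeps the canonical residual-block
truncation semantics — so the sequence length is preserved for any
kernel/dilation pair satisfying the padding rule.

Attention pooling computes `a = softmax(tanh(X w_q))`, `e = aᵀX` with a
learned 128-d query per label. Padded positions are masked to −∞ before
the softmax so the weights form a probability vector over real windows;
zero-padding without masking would silently leak attention mass onto
padding. Each pooled embedding feeds a two-layer MLP (hidden width 64) to
one study logit; window logits come from a shared linear map on the
per-position embeddings.

The multitask loss weights the window term by `w · q_i`, where `q_i` is
the study's proportion of positive windows, and the study term for label
k by `w_k`. The formula is implemented exactly as printed: `q_i = 0`
studies contribute no window loss. An optional `q_floor` (default 0, i.e.
off) is provided as a documented deviation switch for users who want
all-negative studies to exert gradient pressure on the window head. `w`
defaults to 1 and the nine `w_k` default to 1 and come from
configuration; no external competition weights are hard-coded. Training
uses Adam (5 × 10⁻⁴, decayed ×0.9 every 20 steps, batch 64, 200 epochs at
full scale) and keeps the minimum-validation-loss checkpoint.

Study-level labels are predicted independently; hierarchical consistency
between them (e.g. a negative study implies no left PE) is deliberately
not enforced, reproducing the admitted limitation of the approach.

## Evaluation

AUROC is the Mann–Whitney statistic computed from midranks and is tested
against all-pairs enumeration. DeLong 95% confidence intervals use the
fast placement-value formulation, cross-checked in tests against the
naive O(mn) structural-components computation and a bootstrap.
"Maximize both sensitivity and specificity" is operationalized as
Youden's J on a 0.05-granularity probability grid (ties: higher
sensitivity, then lower threshold); the J criterion is an interpretation,
stated as such, of an informal selection rule. Feature-space separation
reports Manhattan distances to and between class centroids; the 2-D
scatter for visual inspection uses classical MDS of the Manhattan
distance matrix, which matches the metric of the reported statistics (a
t-SNE embedding would serve the same illustrative purpose; MDS keeps the
plot deterministic and dependency-free).

## Interpretability

Per-label attention rows, restricted to real windows and renormalized,
are the saliency maps; argmax ties resolve to the lowest index. Grad-CAM
is applied to the phase-1 backbone only. The target activation is the
output of the deepest residual stage (the input to global average
pooling); because pooling is global, the logit gradient there is
spatially constant per channel and the channel importances reduce to the
head-path gradient. The heatmap is the rectified importance-weighted sum
of activation channels, trilinearly upsampled to the window grid, and is
invariant to adding constants to the logit.

## Synthetic data: what it emulates and what it does not

Two generators make every stage testable without patient data.

**Phantom CT studies** are piecewise-constant HU volumes plus Gaussian
noise: soft-tissue background (+40 HU), an axis-aligned lung box
(−800 HU), and bright spherical emboli (+300 HU, within the PE display
window) planted inside the lung. Slice labels are induced by embolus
spans; study position labels derive from embolus x-position against the
volume midline (central within a ±width/8 band); attributes with no
geometric analogue (chronic, indeterminate, RV/LV) come from spec flags
so all nine heads stay exercised. Defaults for the pipeline demonstrations
are 10 studies of 36 slices at 2.5 × 1 × 1 mm spacing, 48 × 48 px slices,
noise SD 15 HU — small enough to preprocess in seconds, large enough that
resampling, lung cropping and window splitting are all non-trivial. One
top-level seed derives per-study streams, so adding a study never
perturbs earlier ones.

**Synthetic feature sequences** emulate phase-1 output: 512-d standard
normal features, with positive windows shifted by a vector of total L2
magnitude `positive_shift` (in SD units, spread evenly across
dimensions). A scalar of 5 therefore means 5-SD class separation —
comfortably learnable, matching the well-separated clusters phase 1 is
expected to produce. Positive studies carry one contiguous positive run
(2–5 windows); the default label rule assigns left/right/central PE by
the run's position in the sequence, so study labels are a learnable
function of window structure. Sequence lengths default to 8–20 windows
and a third of studies are positive — roughly the positivity regime of
public PE datasets.

What the phantoms do *not* model: anatomy, vessels, contrast timing,
artifacts, or realistic texture. Passing tests therefore demonstrate that
the pipeline's mechanics (geometry, labeling, optimization, attention,
evaluation) are correct and that planted signal is recovered; they say
nothing about clinical performance on real CTPA, which requires the full
training dataset and GPU-scale computation and is explicitly out of scope.

## Numerical and design choices

* Coordinates are 0-based with half-open boxes throughout; volumes are
  stored `H × W × D` (slice = `vol[, , z]`) with spacing recorded
  `(z, y, x)`.
* Image resampling uses align-centers sampling; rotation fills outside
  the support with zero and re-clamps to [0, 1].
* The window-loss weight `w` and the per-label `w_k` are configuration
  with default 1; the reference work does not print values for them.
* Dilation indexing is zero-based (dilations 1, 2); one-based indexing
  (2, 4) is a readable one-line change in `tcn_config()`.
* Attention-mass diagnostics use the `negative_for_pe` head: it is the
  only study label that is a pure function of window positivity, so its
  attention must localize PE windows; positional labels can legitimately
  be decoded from sequence position instead.
* Epoch budgets in the test profiles (8 phase-1, 30 phase-2 epochs;
  15 in the bundled acceptance runs) are chosen so training converges on
  the synthetic generators at desk scale; problem sizes used by the
  acceptance script are 400/60/80 train/validation/test sequences for
  phase 2 and 32 phantom windows for the phase-1 overfit check.

## Known limitations

* No DICOM reader: studies enter as NIfTI volumes or in-memory raw
  series with slope/intercept/z-positions supplied.
* No batch normalization and no pretrained weights in the backbone;
  full-scale training would want both.
* Predicted study labels can be mutually inconsistent (by design, see
  above).
* The pure-R engine is fast enough for test-profile models only; the
  full-scale configuration is provided for completeness, not speed.
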