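---
title: "Anatomically informed prostate lesion detection: models and methods"
author: "SymZonal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomically informed prostate lesion detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinically significant prostate cancer (csPCa) is read on multi-parametric
MRI (mpMRI): a T2-weighted sequence (T2WI), the apparent diffusion
coefficient map (ADC) and a high-b-value diffusion acquisition. Two
anatomical facts complicate voxel-level detection models that treat all
lesions identically:

1. **Zonal appearance differences.** Under PI-RADS reading rules, a lesion
   in the peripheral zone (PZ) is established chiefly by diffusion evidence
   (dark on ADC, bright on high-b DWI), while a lesion in the transition
   zone (TZ) additionally requires corroborating T2WI evidence. A loss
   that scores both zones with one binary target discards this structure.
2. **Bilateral symmetry of benign mimics.** Benign prostatic hyperplasia
   nodules and the central zone look locally identical to cancer on all
   three channels — dark on T2WI and ADC, bright on high-b — but tend to
   occur in left-right symmetric pairs, whereas cancer is almost always
   unilateral. A model that only sees local appearance cannot rank these
   mimics below true lesions, and they become systematic false positives.

`SymZonal` implements the two corresponding priors: a *hierarchical zonal
loss* and a *symmetric-aware dual-path encoder-decoder*, together with the
full evaluation protocol (local-maxima detection, 5 mm adjudication, FROC,
patient-level ROC with bootstrap CIs) and a synthetic phantom generator so
that every stage is testable without clinical data.

## Hierarchical zonal labels and the zonal loss

Each voxel carries a two-component label $m = (m_0, m_1)$:

$$
m = \begin{cases}
(1,1) & \text{lesion voxel in the TZ}\\
(1,0) & \text{lesion voxel in the PZ}\\
(0,0) & \text{otherwise.}
\end{cases}
$$

Channel $m_0$ is the diffusion-related lesion evidence shared by all
lesions; $m_1$ is the *additional* T2WI evidence required of TZ lesions.
The pattern $(0,1)$ — T2WI evidence without the common lesion signal — is
undefined, so valid labels always satisfy $m_1 \le m_0$
(`encodeHierarchical()` enforces this by construction and the
`HierLabelMap` validity check re-asserts it).

The model emits a per-voxel probability vector $p = (p_0, p_1)$ through
independent sigmoids (a softmax could never produce the legal target
$(1,1)$). The plain two-channel cross-entropy would score the channels
independently and leave predictions with $p_1 > p_0$ — the forbidden
pattern — unpenalized. The modified cross-entropy therefore substitutes
constrained probabilities before taking logarithms:

$$
p_0' = \begin{cases} p_0 & m_0 = 1\\ \max(p_0, p_1) & m_0 = 0\end{cases}
\qquad
p_1' = \begin{cases} \min(p_0, p_1) & m_1 = 1\\ p_1 & m_1 = 0\end{cases}
$$

For a background voxel, a spurious $p_1 > p_0$ inflates $p_0'$ through the
max and is punished in channel 0; for a TZ-lesion voxel, $p_1 > p_0$ caps
$p_1'$ at $p_0$ through the min, so the only way to earn credit on channel
1 is to first raise $p_0$. Both selections propagate gradients through the
chosen branch (the subgradient of max/min); exact ties route the gradient
to channel 0, a fixed precedence that makes training deterministic.

The zonal loss is the focal form of this modified cross-entropy,

$$
\mathcal{L}^{ZL} = \sum_v \sum_{k \in \{0,1\}}
-m_k (1-p_k')^\gamma \log p_k' - (1-m_k) (p_k')^\gamma \log (1-p_k'),
$$

which down-weights well-classified background voxels — the overwhelming
majority — in favor of the rare lesion voxels. At $\gamma = 0$ it reduces
exactly to the modified cross-entropy (`modifiedCE()`); the package also
provides the plain binary focal loss (`focalLossBinary()`) as the ablation
baseline.

Numerical choices:

* $\gamma$ defaults to 2, the canonical focal-loss exponent; it is
  configurable via `lossConfig()`.
* Probabilities are clamped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-7}$ before logarithms so the loss stays finite at
  saturated outputs.
* The definition sums over voxels; `reduction = "mean"` divides by the
  voxel count and is what the trainer uses, so that learning rates do not
  depend on volume size. Both reductions are exposed because the summed
  form is the definition while the averaged form is the practical one.

## The symmetric-aware network

`buildModel()` constructs a three-level 3D U-Net-style encoder-decoder
(default channel widths 64/128/256, four ConvBlocks per encoder level; a
ConvBlock is a 3×3×3 convolution, LeakyReLU (slope 0.01), then instance
normalization, in that order). The symmetric-aware part:

* The network takes **two inputs**: the original five-channel stack (T2WI,
  ADC, high-b, TZ mask, PZ mask) and the same stack mirrored across the
  width (left-right) axis. One encoder instance processes both — weight
  sharing holds *by construction*, there is simply no second parameter
  set — so the two feature maps are directly comparable.
* At every level above the bottleneck the two feature maps are
  concatenated channel-wise and fused by a **BridgeBlock** (two
  ConvBlocks). Because the mirrored path is not flipped back, each spatial
  location sees its own features next to its contralateral counterpart's:
  symmetric structures produce near-identical pairs, unilateral lesions do
  not, and that difference is exactly the feature the bridge can learn to
  use.
* The decoder concatenates each bridge output with the ×2-upsampled
  features from below and finally maps to per-channel sigmoids, aligned
  with the original orientation.

Design points that were genuinely open and how they were settled:

* **Bottleneck fusion.** Fusion is specified only for levels above the
  bottom; by default only the original-path bottleneck features feed the
  decoder and the mirrored bottom features are discarded. A `fuseBottom`
  flag adds a bottom bridge for users who want full fusion.
* **Resampling operators.** Downsampling is a stride-2 convolution and
  upsampling a kernel-2/stride-2 transposed convolution, the nnU-Net
  convention.
* **Single-path ablation.** The symmetry-off arms feed the original stack
  to *both* encoder inputs rather than deleting the mirrored path, so all
  four ablation arms have identical parameter counts and the comparison
  isolates the information, not the capacity.
* **Head initialization.** The final 1×1×1 convolution initializes near
  zero (sd 0.01), so the untrained output starts near 0.5; `finalInit =
  "zero"` makes that exact.

The engine behind the model is a compact, self-contained set of
Rcpp/RcppArmadillo kernels: im2col+GEMM convolutions with analytic
backward passes (the stride-1 input gradient is itself a correlation with
the channel-transposed, spatially flipped kernel, so it also runs through
GEMM), a hand-derived instance-norm backward, and an Adam optimizer.
Every kernel is verified against finite differences in the test suite, and
the whole network's gradient is checked end to end.

## Preprocessing

`preprocessCase()` chains three standardizations:

1. **Center-line alignment** (`alignCenterAxis()`): the in-plane line from
   the whole-gland centroid to the TZ centroid is rotated to vertical, so
   left-right anatomical symmetry coincides with the mirror axis the
   network uses. One global angle per case; images interpolate bilinearly,
   masks by nearest neighbor.
2. **Center crop** (`centerCrop()`), default 128×128 in-plane, depth
   untouched.
3. **Intensity normalization** (`normalizeCase()`): T2WI and high-b are
   min-max scaled to [0,1] per patient; ADC, being quantitative, is
   clipped at a patient-independent value and divided by it so absolute
   diffusion levels stay comparable across patients. The default clip is
   3000 (units of 10⁻⁶ mm²/s), a conventional upper bound for prostate
   tissue; it is configurable and recorded in the JSON provenance sidecar.

Bias-field correction and inter-sequence registration are upstream
responsibilities; the phantoms are generated pre-aligned.

## Detection and evaluation

* **Candidates** are strict local maxima of the detection channel over the
  26-neighborhood with score ≥ 0.1, with greedy suppression of maxima
  within 5 mm of a stronger one. The detection channel defaults to $p_0$,
  the "lesion anywhere" channel of the hierarchy; $p_1$ only adds
  TZ-specific evidence ("p1" and "max" are available).
* **Adjudication**: a point is a true positive iff it lies within 5 mm
  (world distance) of the *nearest lesion-mask voxel* — a conservative,
  shape-aware reading that absorbs histopathology-to-MRI registration
  mismatch. Extra TPs on one lesion are neither new TPs nor FPs.
* **FROC**: a full sweep over the union of detection scores yields
  (mean FP/patient, lesion sensitivity) pairs; sensitivities at the
  standard operating points 0.5–2.5 FP/patient follow the step-function
  convention (the best sensitivity at no more than the FP budget), so
  reported numbers are bit-for-bit reproducible.
* **Patient level**: the patient score is the maximum of $p_0$; AUC is the
  tie-aware Mann-Whitney statistic; confidence intervals come from a
  1000-replicate percentile bootstrap over patients.
* **Cross-validation**: `makeCVSplits()` partitions ids into folds whose
  sizes differ by at most one (652 ids at $k=5$ gives 131/131/130/130/130).

## The phantom generator

`generatePhantom()` builds the study conditions the method assumes, not a
physical MR simulation. Anatomy: a centered prostate ellipsoid scaled to
the field of view, an inner TZ ellipsoid shifted anteriorly, and the PZ as
the remaining shell — all exactly mirror-symmetric about the mid-width
axis. Intensities are zone-wise base levels with a smooth radial taper
(T2WI: PZ bright, TZ intermediate; ADC: prostate high, background low;
high-b: mildly elevated TZ), additive lesion/mimic contrast offsets, and
i.i.d. Gaussian noise whose SD is a fraction (default 0.04) of each
channel's noiseless dynamic range, making the signal-to-noise ratio
comparable across channels.

Content:

* **Lesions** are spheres (radius drawn from 5–7 mm at full resolution)
  placed at least 3 mm off the midline so each one breaks symmetry, wholly
  inside the gland, with majority-zone attribution matching the requested
  zone. TZ lesions darken T2WI and ADC and brighten high-b; PZ lesions
  darken ADC and brighten high-b strongly but perturb T2WI only weakly.
* **Mimic pairs** are two blobs at exact mirror positions carrying the
  TZ-lesion-like contrast — locally indistinguishable from cancer — and
  are excluded from the lesion mask. They are the false-positive traps the
  symmetric-aware architecture exists to defuse.
* Placement is rejection sampling with a bounded attempt budget; an
  over-crowded spec fails loudly rather than silently dropping objects.
  A single RNG stream derived from the spec seed governs everything, so a
  spec reproduces its case bit for bit.

The default grid is 16×128×128 at 3 / 0.625 / 0.625 mm, matching the
in-plane resolution and crop size the method targets, so the 5 mm
adjudication radius and FROC behave realistically.

What the phantom does **not** emulate: MR physics (no bias fields, no
partial-volume or Rician noise), anatomical variability of real glands,
multi-focal or irregularly shaped tumors, and imperfect zonal
segmentations. Passing phantom tests therefore demonstrates that the
algorithms implement their definitions and that the symmetry prior works
where its premise holds — not clinical performance.

## The scaled ablation study

`runSymmetryStudy()` is the package's reference experiment, sized for a
single CPU: 50 phantoms on an 8×32×32 grid at 3 / 2.5 / 2.5 mm (the same
80 mm in-plane field of view at coarser resolution; lesion radii 4–6 mm),
one mimic pair per case, one lesion in two of every three cases
(alternating TZ/PZ, the rest lesion-free so patient-level AUC is defined);
40 cases train a reduced network (encoder widths 8/16/32, one ConvBlock
per level) for 5 epochs with Adam at learning rate 10⁻³ and batch size 2,
in all four ablation arms on the identical split and seeds; 10 held-out
cases are evaluated by FROC and patient AUC.

Because the mimics carry exactly lesion-like local contrast, a
symmetry-blind model has no information with which to rank them below true
lesions, so its FROC must pay for sensitivity with mimic false positives;
the dual-path model sees the left-right feature discrepancy and can
suppress them. The headline comparison is the mean FP/patient required to
reach 0.8 lesion sensitivity, and the acceptance suite checks that the
symmetric+zonal arm is no worse than the single-path focal baseline in a
majority of five seeded replicates — a deliberately qualitative claim, as
individual CPU-scale runs are noisy.

## Known limitations

* Training is full-volume, single-threaded and CPU-bound; the full-size
  configuration (64/128/256 channels on 16×128×128 grids) is implemented
  and tested for correctness but is not practical to *train* at scale in
  this engine — it exists so the architecture is faithful, while the
  reduced configuration carries the experiments.
* The per-epoch early-stopping criterion watches the *training* loss
  (validation-based stopping is a trivial extension but is not what the
  protocol specifies).
* The hierarchical encoding assigns lesion voxels that fall outside both
  zonal masks the PZ-style label $(1,0)$ — they keep the common lesion
  evidence but claim no TZ-specific signal. Real zonal masks are
  imperfect; the encoder warns with the affected voxel count.
* The phantom's mimic pairs are exactly symmetric (optionally jittered by
  placement randomness only); real BPH symmetry is approximate, so the
  study measures the prior under its cleanest premise.
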