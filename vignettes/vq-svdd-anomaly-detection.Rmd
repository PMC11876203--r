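---
title: "Slice-based anomaly detection with a vector-quantized autoencoder and deep SVDD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-based anomaly detection with a vector-quantized autoencoder and deep SVDD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Screening chest CT produces many slice images per examinee and few readers.
One-class (anomaly-detection) approaches sidestep the need for labelled
lesions of every disease type: a generative model is trained on **normal**
volumes only, and an examinee is flagged when their images deviate from what
the model can reproduce. `vqsvdd` implements such a scheme for stacks of 2D
grayscale slices: a vector-quantized autoencoder (VQ-VAE) with an inner
encoder/decoder pair whose latent vectors are pulled into a minimal
hypersphere (deep SVDD).

## The model

Five modules are chained per slice image $x \in [0,1]^{s \times s}$:

1. **Encoder 1** compresses $x$ to a latent-variable map
   $z_e(x) \in \mathbb{R}^{H \times W \times D}$ with $H = W = s/4$ —
   one quarter of the input per side, large enough to retain fine structure.
2. **Encoder 2** compresses $z_e(x)$ to a single vector $z(x)$ of dimension
   $m \ll HWD$. This bottleneck is the anomaly-suppression mechanism: the
   quarter-size map has ample redundancy to reproduce *any* structure,
   including lesions; the vector does not.
3. **Decoder 2** up-samples $z(x)$ back to a map $z_d(x)$ of the same size
   as $z_e(x)$.
4. **Quantization** replaces each channel-direction vector of $z_d(x)$ by
   its nearest neighbour among $K$ learned codebook embeddings $e_k \in
   \mathbb{R}^D$ (ties toward the smallest index), giving $z_q(x)$.
5. **Decoder 1** reconstructs $\hat{x}$ from $z_q(x)$.

A slice's anomaly score is

$$S(x) = \lVert x - \hat{x} \rVert_2^2 + \lVert z(x) - c \rVert_2^2,$$

the summed squared reconstruction error plus the squared distance of the
latent vector from the hypersphere center $c$; an examinee's representative
score is the **maximum** over their slices, and a case is called abnormal
when it exceeds a threshold chosen to maximize the Youden index
(sensitivity + specificity − 1) over the representative scores.

The reference architecture uses $D = K = 128$ for 256-px inputs. All widths
are configurable through `arch_config()`; Encoder 2 deliberately has **no
output activation and no normalization layers** — both are known routes to
hypersphere collapse, where a bias term or a saturating nonlinearity lets
the network shrink all latents to a constant and trivially minimize the
SVDD term.

## Losses and the three-step protocol

Training uses only normal volumes (`train_vq_svdd()` rejects anything
else). Reconstruction quality is measured by a summed squared error plus
`1 − MS-SSIM`; the multi-scale structural similarity

$$\mathrm{MS\_SSIM}(x,\hat{x}) = [L(x,\hat{x})]^{\alpha}
  \prod_{j=0}^{M} [C_j]^{\beta} [S_j]^{\gamma}$$

evaluates brightness (L), contrast (C) and structure (S) comparisons from
windowed local moments, with C and S recomputed after each 2×2
average-pool halving and L taken at the coarsest scale. Stabilization
constants are $\delta_1 = 10^{-4}, \delta_2 = 9 \times 10^{-4},
\delta_3 = 4.5\times10^{-4}$; exponents default to 1 and $M = 5$.

Two structure-term forms are provided. The default `"standard"` form
normalizes the covariance by $2\sigma_x\sigma_{\hat{x}} + \delta_3$, which
keeps S dimensionless and equal to 1 for identical inputs. The `"literal"`
form divides by $\sigma_x + \sigma_{\hat{x}} + \delta_3$ instead —
dimensionally inconsistent, but included (and tested) as a documented
variant because it appears in print in this line of work. Both are exposed
via `msssim_params(structure_form=)`.

**Step 1** trains the outer autoencoder only (Encoder 1, codebook,
Decoder 1), with the latent map bypassing the inner pair:

$$\mathcal{L}_1 = \lVert x-\hat{x}\rVert_2^2 + (1 - \mathrm{MS\_SSIM}) +
 \lVert \mathrm{sg}[z_e] - e \rVert_2^2 + \lambda \lVert z_e -
 \mathrm{sg}[e] \rVert_2^2,$$

where `sg` is the stop-gradient operator: the third term updates only the
codebook, the fourth (commitment, $\lambda = 0.25$) only the encoder, and
the non-differentiable argmin is bridged by the straight-through estimator
(gradients at $z_q$ are copied to the pre-quantization map unchanged). The
test suite audits all three routing rules by finite differences.

**Step 2** trains the full network without the SVDD term, adding the
consistency term $\lVert z_e - z_d \rVert_2^2$ (and using $z_d$ in the
codebook/commitment terms). Afterwards the hypersphere center is
initialized as the mean of $z(x)$ over all training slices.

**Step 3** adds $\lVert z(x) - c \rVert_2^2$ and refreshes $c$ **every
epoch** as the mean of the latents observed during that epoch (a
replacement, not a running average). A `center_refresh = "full_pass"`
option recomputes the mean with a dedicated forward pass instead; the
default reuses the epoch's minibatch latents, which is cheaper and
equivalent up to within-epoch drift. The center is treated as data — no
gradient ever updates $c$ directly.

Reference hyperparameters: Adam, learning rate $10^{-4}$, batch 64, up to
200 epochs per step. The reconstruction L2 term is the *summed* squared
error as written above, not the pixel mean; this sets its scale relative
to the MS-SSIM term (hundreds vs. ≤ 1 on 64-px slices) and is worth
remembering when reading loss histories.

## The synthetic phantom benchmark

The package ships a seeded chest-phantom generator (`phantom_config()`,
`generate_normal_volume()`, `inject_anomaly()`, `generate_dataset()`)
standing in for a private screening database. Each examinee is a stack of
8–12 slices (64 px by default): an elliptical body wall (intensity 0.6)
encloses two darker lung fields (0.2) containing a vessel-like vascular
tree (bright branches, ≈0.5) that radiates from a per-lung hilum along
case-seeded angles and varies smoothly along the stack; slices are
rendered at 2× resolution and average-pooled, emulating the soft edges of
resampled CT. Gaussian pixel noise (SD 0.02) is added and values are
clamped to [0, 1].

The generator's design goal is the *statistical regularity the method
assumes*: normal anatomy is consistent across examinees (comparable
vascular load per unit lung, near-constant gross geometry), while injected
anomalies are localized deviations. Three lesion kinds mirror
intrapulmonary disease: spiculated, internally textured bright **nodules**
(malignancy-like high-frequency structure that a normals-only model cannot
restore), diffuse streaky **consolidations**, and structure-free dark
**voids** (emphysema-like; these *remove* structure, which makes them the
hardest kind for any reconstruction-based score — a limitation this method
family shares). Anomalies are placed wholly inside a lung field on a run
of contiguous slices, and per-slice masks/flags record the ground truth.

What passing benchmarks on these phantoms does **not** show: performance
on real CT. The phantoms have no HU calibration, no 3D lesion morphology,
no scanner artifacts, and far less anatomical diversity than a screening
population; the benchmark validates the machinery (losses, routing,
training dynamics, scoring, evaluation design), not clinical accuracy.

## Scaled-down benchmark configuration

Desk-scale runs use 64-px phantoms, 20 normal training cases (~200
slices), and 10 epochs per step. Several training choices differ from the
reference values because ~200 slices × 10 epochs gives only a few thousand
optimizer steps (the reference setting has hundreds of thousands):

* **batch size 1–2 and learning rate $2\times10^{-3}$** — per-epoch cost
  here is nearly batch-size independent, so small batches buy many more
  Adam steps; convergence is step-limited, not data-limited;
* **codebook initialized from encoder samples**
  (`codebook_init = "encoder_sample"`): K latent vectors drawn from the
  untrained encoder replace the uniform $[-1/K, 1/K]$ init, which at this
  step budget cannot migrate to the encoder's operating region (the
  codebook term diverges while chasing it);
* **`pretrained_lr_factor = 0.1`** in Steps 2–3: the freshly added inner
  pair trains at the full rate while the pretrained outer modules follow
  slowly. Without this, the symmetric consistency term drags $z_e$ toward
  the initially random $z_d$ and the whole latent space collapses to a
  point within a few epochs;
* **cosine learning-rate annealing** over each step's epochs.

All of these default to the reference behaviour (uniform init, factor 1,
constant rate) in `train_config()`.

The benchmark's lesion sizes (radius 7–8 px, 4 contiguous slices, deltas
+0.4 / −0.15) are chosen for class separability at 64 px rather than for
epidemiological realism: at desk scale the representative score's
between-case spread is governed by how unevenly the model generalizes
across unseen vessel arrangements, and smaller or fainter lesions sit
below that spread. On this benchmark the full model reaches
representative-score AUC ≈ 0.72–0.90 across seeds (the VAE baseline is
close, unlike at full scale, because blurry reconstructions of these
simple phantoms rank cases stably), and abnormal-slice fidelity (SSIM,
RMSE) is reliably worse than normal-slice fidelity — the qualitative
signature the method predicts.

## Evaluation design

`sixfold_split()` reproduces the screening-study protocol: normal cases
are shuffled into six near-equal subsets; each fold trains on four,
validates on one, tests on one, and **every abnormal case joins every
fold's test set** — abnormal data never influence training. `evaluate_fold()`
reports AUC (trapezoidal ROC via pROC, which equals the Mann–Whitney
statistic with half credit for ties) plus the Youden-index operating
point. The Youden threshold is scanned over midpoints of consecutive
distinct scores (plus one cut above the maximum); ties in J break toward
higher specificity, the conservative choice for a screening population
dominated by normals; a case is abnormal only when its score is *strictly*
above the threshold. The threshold is fit on the same test scores it
classifies — an in-sample threshold, reported as such. `evaluate_cv()`
aggregates per-fold metrics (mean ± SD) and compares models with a
two-sided paired t-test on the per-fold pairs (df = folds − 1).

Reconstruction fidelity (`fidelity_comparison()`) pools RMSE, PSNR and
SSIM over **all slices of normal cases** versus **only the flagged slices
of abnormal cases**; unflagged slices of abnormal cases belong to neither
group.

## Numerical choices and degenerate inputs

* MS-SSIM scales auto-reduce so the coarsest scale keeps ≥ 8 px per side
  ($M_{\mathrm{eff}} = \min(M, \log_2 s - 3)$, with a warning), and the
  window is truncated and renormalized when wider than the current scale;
  images below 8 px are an error.
* Windowed variances are clamped at 0 before the square root; the
  structure-term gradient guards $\sigma_{\hat{x}} = 0$ with a $10^{-12}$
  floor. The analytic MS-SSIM gradient (needed because every loss
  backpropagates through it) is validated against finite differences to
  $10^{-6}$.
* Quantization ties break toward the smallest codebook index, making
  scoring fully deterministic.
* `minmax_scale()` maps a constant volume to all zeros with a warning;
  scaling is per-volume, not per-slice, so one examinee's tissue keeps a
  consistent gray level across slices (per-slice scaling would not).
* Bicubic resampling uses the Keys $a = -0.5$ kernel with edge
  replication; resizing to the input size is an exact identity.
* An empty Step-3 epoch leaves the center unchanged with a warning; an
  empty training set is an error.
* `update_center()` replaces the center with the current epoch's mean; two
  consecutive epochs never blend.

## Known limitations

* Voids (emphysema-like lesions) produce the weakest score response: a
  flat dark patch is easy to reconstruct, so only the removed structure
  contributes error. This mirrors the method's published behaviour on
  real emphysema.
* The SVDD distance term contributes little at desk scale — with few
  epochs the inner encoder maps normal and abnormal latents to similar
  neighbourhoods, and the score is dominated by the reconstruction term.
  For the same reason the hypersphere does not shrink reliably in short
  runs: the unit-weight distance term (~0.1–0.2) is orders of magnitude
  below the reconstruction terms (~20–50 on 64-px slices), so within ten
  Step-3 epochs the latent cloud's drift under the reconstruction
  objectives can outweigh the weak inward pull (observed for one of three
  benchmark seeds). With the reference epoch budget, where reconstruction
  has largely converged during Steps 1–2, the term governs late-stage
  dynamics instead.
* The fixed reference architecture (stride-2 convolutions, residual
  blocks) honors the documented structural constraints but is not a
  layer-for-layer replica of any particular diagram; all widths are
  configurable.
* Training at 256 px with the reference hyperparameters is supported by
  the code but far outside desk-scale budgets.
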