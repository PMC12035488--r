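---
title: "Super-resolving synthetic brain metabolite maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolving synthetic brain metabolite maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsisr)
```

## The problem

Magnetic resonance spectroscopic imaging (MRSI) measures metabolite
concentrations in vivo, but at grids far coarser than anatomical MRI:
a clinical brain MRSI slice is typically 32 × 32 voxels, against 128 × 128
or finer for structural contrasts. At a 220 mm in-plane field of view and
10 mm slice thickness those grids correspond to 6.875 × 6.875 × 10 mm and
1.71875 × 1.71875 × 10 mm voxels. `mrsisr` implements a complete pipeline
for studying learned four-fold upscaling of such maps: a seeded brain-slice
phantom generator, a literature-derived synthesis model producing paired
high/low-resolution metabolite maps, an attention-based convolutional
super-resolution network with its training loop, classical interpolation
baselines, and a metric/significance evaluation suite.

Everything runs on synthetic data; no imaging downloads or external model
weights are required.

## The phantom generator

Real studies of this kind start from glioma MRI cohorts segmented into gray
matter (GM), white matter (WM) and cerebrospinal fluid (CSF) partial-volume
maps. `generate_subject()` replaces that input with a parametric anatomy:

* an elliptical head whose radius is modulated by a smooth random field,
* a peripheral CSF rim, a cortical GM band, central WM, and two ventricles
  (all *soft* occupancies obtained from logistic transitions, so
  `gm + wm + csf <= 1` holds pixelwise with the remainder background;
  `binarize = TRUE` hardens them to labels),
* a contiguous tumor blob (thresholded Gaussian bump plus smoothed noise,
  largest connected component) carrying an LGG/HGG grade label, whose
  extent waxes and wanes smoothly across slices,
* a FLAIR slice with suppressed CSF, GM brighter than WM, a multiplicative
  bias field, mild pixel noise, and a hyperintense tumor.

Slice selection follows the rule used for real cohorts: a slice enters the
dataset only if the mean FLAIR intensity over tumor pixels strictly exceeds
the mean intensity of the whole slice; 5–10 such slices per subject are kept
(`select_slices()`).

What the phantom deliberately does **not** emulate: 3-D anatomical realism,
registration or skull-stripping artifacts, acquisition physics (lineshapes,
B0 inhomogeneity, partial-volume bleed), or pathology beyond a single
compact lesion. Consequently, passing tests here demonstrate that the
*pipeline and model mechanics* work — not that the trained weights transfer
to clinical MRSI.

## From tissues to metabolite maps

`concentration_table()` carries literature concentration ranges (mM) with
point estimates for tCr, tCho and NAA in GM, WM and tumor tissue, plus
tumor and nontumor ranges for the diagnostic ratios tCho/NAA and tCho/tCr.
Point estimates are range midpoints (`estimated_concentration()`); the
printed nontumor ratio estimates are retained verbatim even where they are
not exact midpoints, treating the published table as authoritative. CSF is
metabolite-free.

Tumor grade enters through the ratio ranges: `grade_threshold()` splits a
tumor ratio range at its average; LGG lesions draw from the lower sub-range
and HGG lesions from the upper (`tumor_value()`). In deterministic mode the
sub-range midpoint is used; in sampled mode a seeded uniform draw adds
between-subject variability, with one draw per subject and map type so a
lesion keeps a single metabolic profile across its slices.

`synthesize_map()` forms the 128 × 128 map as

\[ v(p) = C_{GM}\,gm(p) + C_{WM}\,wm(p) + 0 \cdot csf(p), \]

with the tumor value replacing the tissue contribution inside the mask.
The replacement (rather than addition) avoids double-counting tissue under
the lesion; a strictly additive variant is available via
`tumor_additive = TRUE` for fidelity experiments. Maps are normalized to
`[0, 1]` by their maximum (`normalize_map()`), and the 32 × 32 counterpart
is produced by 4 × 4 block averaging (`downsample_map()`), chosen because
it mimics the signal integration of a larger MRSI voxel and conserves the
map mean exactly. `build_dataset()` emits five examples per selected slice
(three metabolites, two ratios); each pairs the high-resolution target with
a two-channel low-resolution input — the downsampled map plus the FLAIR
slice block-averaged to 32 × 32 and min–max normalized, supplying anatomical
context at the same grid as the network input.

## The network

`srnet_config()` / `build_srnet()` define a ×4 single-image super-resolution
network:

* a 3 × 3 shallow convolution to `base_channels` features;
* a body of `n_pairs` pairs of a **high-frequency attention block (HFAB)**
  followed by a **gated depthwise-convolution feed-forward block (GDFN)**,
  with two long skip connections from the shallow features — one into the
  body midpoint, one into the body end;
* a sub-pixel head: twice (3 × 3 convolution to 4 × channels, depth-to-space
  ×2), then a 3 × 3 convolution to one channel, linear output.

The HFAB's attention branch is batch-norm → 3 × 3 reduce → enhanced residual
block (ERB: 1 × 1 expand, 3 × 3 convolve, 1 × 1 contract, residual) →
3 × 3 restore → batch-norm → sigmoid, producing a per-position gate in
`[0, 1]`; the block output is `x + x * gate`. Batch normalization uses batch
statistics during training and stored running statistics at inference, so
`upscale()` is deterministic. The GDFN runs two parallel 1 × 1 + depthwise
3 × 3 projections, gates one by a smooth sigmoid-weighted linear activation,
multiplies elementwise, and projects back with a residual add.

Choices the architecture description leaves open, fixed here and exposed in
the configuration: channel widths (`base_channels = 48`, derived from the
≈650,000-parameter budget; the default build reports 648,769), skip
endpoints (midpoint and end), the upsampler (sub-pixel convolution, the
standard parameter-efficient choice for ×4), ReLU activations inside the
attention branch, and a linear output head clipped to `[0, 1]` at inference
(keeping the loss well-scaled; a sigmoid head is available via
`sigmoid_head = TRUE`). The GDFN's closing 1 × 1 projection is
zero-initialized so every body block starts as an identity: without this the
multiplicative gating compounds activation magnitudes across the stacked
pairs and training diverges. The sub-pixel stage convolutions use ICNR-style
initialization — identical kernels across each depth-to-space group — so the
head starts as a checkerboard-free nearest-neighbor upsampler, and the
output convolution is initialized small (0.1× gain) so early training is not
spent shrinking the output scale. The `"reduced"` preset (16 channels,
4 pairs, ≈48,000 parameters) is the configuration used for CPU-scale
experiments.

## Training

`train_srnet()` (or the one-call `srnet_fit()`) minimizes the log hyperbolic
cosine reconstruction loss — quadratic for small residuals, linear for large
ones, smooth throughout — computed stably as
`|x| + log1p(exp(-2|x|)) - log 2`. Optimization is Adam with standard moment
parameters. The reference protocol is batch size 24, learning rate 1e-5,
100 epochs, 30% of *subjects* held out for validation (subject-level
splitting prevents slice leakage between sides; per-map splitting would leak
the same anatomy into both), and augmentation by seeded rotations restricted
to 90° multiples plus horizontal/vertical flips — rigid transforms that need
no interpolation and are applied identically to inputs and target. The
checkpoint with the best validation loss is restored after training (or,
with `swa_from`, the equal-weight average of the final epochs' weights —
stochastic weight averaging, which lands in a flatter, smoother minimum),
and batch-norm running statistics are then re-estimated over the training
set so inference-mode normalization matches the final weights. All
randomness (cohort anatomy, concentration draws, weight initialization,
shuffling, augmentation) derives from one root seed split into named
streams (`derive_seed()`), so full runs are bit-reproducible on one machine.

## Baselines

`nearest_upscale()` replicates each pixel into a 4 × 4 block — the exact
inverse of block averaging on block-constant images. `spline_upscale()`
performs separable natural-cubic-spline interpolation (orders 1 and 2
available) under a fixed half-pixel center convention — output pixel *i*
samples the input at `(i - 0.5)/4 + 0.5` — with reflect padding at the
boundaries and clipping of spline overshoot back to `[0, 1]` for normalized
inputs. The alignment convention is fixed and documented so that metric
values reproduce bit-for-bit.

## Evaluation

`evaluate_methods()` scores every reconstruction against its ground truth:
MSE, RMSE, PSNR (`20 log10(MAX) - 10 log10(MSE)`, with `MAX = 1` for
normalized maps — a fixed dynamic range rather than a per-image maximum, so
values are comparable across maps), and SSIM with the conventional
`k1 = 0.01`, `k2 = 0.03` stabilizers under an 11 × 11 Gaussian window
(σ = 1.5), evaluated over fully-contained window positions. A perceptual
(LPIPS-style) metric requires pretrained external weights and is therefore a
plug-in: register any distance via `set_lpips_backend()`; absent a backend
the metric is omitted rather than failing the run. `summarize_evaluation()`
reports per-method mean and sample (n−1) standard deviation and two-sided
Mann–Whitney U tests for every method pair and metric at the 0.05 threshold
(exact null distribution for tie-free samples of size ≤ 8, normal
approximation with tie correction otherwise). No multiple-testing
correction is applied.

## The desk-scale comparison experiment

`run_comparison_experiment()` exercises the whole pipeline at a size chosen
for a single CPU: 60 subjects, two slices each (42 train+validation / 18
test subjects, split at the subject level; 420 training and 180 held-out
maps), sampled tumor values, the reduced network preset, and at most 20
epochs at batch size 8 and learning rate 3e-3 with 0.95 per-epoch decay,
stochastic weight averaging over the final eight epochs, and batch-norm
re-estimation — a short-budget schedule; the reference protocol (batch 24,
constant 1e-5) is matched to 100 epochs on two orders of magnitude more
maps and barely moves in 20 epochs. The model is evaluated with its
geometric self-ensemble (the mean over the eight dihedral transforms of the
input, each prediction mapped back; `upscale(..., self_ensemble = TRUE)`),
which averages away orientation-dependent reconstruction noise in flat
regions — the dominant residual left by a short training budget. At this scale the absolute metric
values of a fully trained 650k-parameter model on real-anatomy cohorts are
out of reach; what the experiment establishes are the *orderings*: model
MSE below spline below nearest, model SSIM and PSNR above spline, and a
significant model-vs-nearest MSE difference. `run_overfit_check()` is the
companion sanity check: it trains the reduced model on a single fixed batch
of eight phantom examples and reports the final training loss, probing how
far the architecture, gradients and optimizer can memorize under a fixed
step budget. On these phantoms the memorization loss is dominated by the
sharpest structures — the one-pixel tissue transitions and the binary tumor
edge — which bound how small it can get within a short run.

## Numerical notes and limitations

* Degenerate inputs: all-zero maps normalize to themselves (flagged
  normalized); zero MSE reports PSNR `Inf`; empty tumor masks make a slice
  ineligible rather than erroring; an all-ineligible cohort yields an empty
  dataset with a warning.
* `logcosh_loss` is exact for residuals far beyond `cosh` overflow.
* Convolutions are im2col + GEMM in compiled code with zero padding;
  depthwise convolutions use channel groups. Training on one CPU thread is
  deterministic for a fixed seed.
* The phantom's statistical structure (piecewise-constant compartments,
  a single blob lesion, mild smooth fields) is far simpler than clinical
  MRSI; results here bound what the pipeline can show about real data.
* LPIPS comparisons, MINC-format I/O and 3-D modeling are out of scope;
  NIfTI is the on-disk standard, with readers for per-tissue planes or
  labelmaps.
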