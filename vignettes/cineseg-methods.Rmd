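---
title: "Methods: models, parameters and design choices in cineseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cineseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the segmentation
model and its assumptions, the parameters that matter, what the synthetic
phantom emulates (and what it does not), the numerical choices, and the
design decisions made where the design was genuinely open. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The analysis problem

Cine cardiovascular MR acquires a movie of the beating heart over one
cardiac cycle, typically ~10 short-axis slices (in-plane 1.8 × 1.8 mm,
10 mm slice separation from 8 mm thickness + 2 mm gap) and single-slice
long-axis views, 50 frames per cycle, with bright blood pool and mid-grey
myocardium. Manual analysis traces the LV cavity, LV myocardium and RV
cavity at end-diastole (ED) and end-systole (ES); the measures of clinical
interest — chamber volumes, LV mass, stroke volume, ejection fraction,
cardiac output — derive from those contours. `cineseg` automates the
tracing with a per-slice fully convolutional network and reproduces the
downstream quantification and agreement analysis.

## The segmentation network

The network is a multi-scale FCN: five resolution scales of 3 × 3
convolutions (widths 16/32/64/128/256, counts 2/2/3/3/3), each convolution
followed by batch normalisation and ReLU, with factor-2 downsampling
between scales; each scale's output is upsampled to full resolution *in one
step* by a transposed convolution and all five are concatenated before a
three-layer 1 × 1 head and softmax. This differs from a U-Net, which
upsamples iteratively scale by scale; the one-shot upsampling path is
simpler. Excluding transposed convolutions the default variant has 16
convolutional layers; the residual variant keeps scales 1–2 and the head
and replaces scales 3–5 with 4/4/5 identity-skip residual blocks of two
3 × 3 convolutions each, for 33 layers.

Assumptions worth stating:

- **Per-slice 2D analysis.** Slices are segmented independently; no
  through-plane context or temporal propagation is used.
- **Roughly centred hearts.** Inputs are centre-cropped/padded to
  192 × 192; a crop-offset parameter exists for off-centre acquisitions.
- **Per-slice min–max intensity normalisation** to [0, 1]. The range
  convention "normalised to [0, 1]" admits several readings (percentile
  clipping, fixed windowing); min–max per 2D slice was chosen because the
  slice is the network's input unit, and constant slices map to zero.

Open details fixed by this package (the published description does not
pin them down):

- **Downsampling operator**: 2 × 2 max-pooling, consistent with the
  VGG-16 heritage of the architecture. Only the factor-2 side contract and
  the layer counts are treated as the fidelity surface, not the operator
  identity.
- **Upsampler shape**: transposed convolution with stride `2^(s-1)` for
  scale `s`, kernel = 2 × stride, pad = stride/2, projecting each scale to
  a fixed width of 16 channels before concatenation; scale 1 participates
  without upsampling. A fixed projection width bounds the head's input size
  regardless of scale widths.
- **Residual layer accounting**: 33 counts main-path convolutions
  including the head, following the usual residual-network convention that
  1 × 1 projection shortcuts are not counted. Allocating entry convolutions
  per scale *plus* 4/4/5 blocks cannot reach 33 with a 3-layer head, so the
  first block of each scale carries the channel change via a projection
  shortcut instead.
- **Batch-norm statistics**: per-feature batch statistics during training
  with running averages (momentum 0.9) for inference, epsilon 1e-5.
- **Initialisation**: variance-scaled (He) normal weights with an explicit
  seed; gamma 1, beta 0.

## Training procedure

The loss is the mean cross entropy over pixels of −log p(true class), with
probabilities clipped at 1e-12 before the log. Optimisation is Adam,
learning rate 0.001, 50,000 iterations, mini-batches of 20 slices sampled
uniformly with replacement; no learning-rate decay and no early stopping
(the schedule is a fixed iteration count). Adam's β₁/β₂/ε are the
conventional 0.9/0.999/1e-8 — only the method and the rate are prescribed
upstream.

Augmentation is applied on the fly per mini-batch: random translation
(±15 px), rotation (±15°), scaling ([0.9, 1.1]), and intensity variation —
implemented as both multiplicative ([0.9, 1.1]) and additive (±0.05)
because the published wording ("intensity variation") does not choose;
each component is configurable and symmetric about the identity. Spatial
transforms use bilinear interpolation for images and nearest-neighbour for
labels (so the label alphabet is closed under augmentation), and images are
re-clipped to [0, 1]. The mild default ranges reflect roughly-centred
acquisitions; wider ranges would be appropriate for less standardised data.

**Fine-tuning** adapts a trained network to a dataset with a reduced label
scheme (e.g. LV-only annotation): the final 1 × 1 prediction layer is
re-initialised to the new class count — keeping the two 64-wide head layers
pretrained — labels are remapped by structure name, and structures absent
from the new scheme are excluded from the loss by masking their pixels out
of the mean. The default fine-tuning schedule is 10,000 iterations.

## The synthetic phantom: what it is and is not

The phantom states a world matching the acquisition geometry above:
192 × 192 × 10 × 50 grids at (1.8, 1.8, 10) mm, 20 ms frame interval (a
1 s cycle, heart rate 60). The LV is a cylinder whose endocardial radius
follows a cosine between its ED value (frame 1) and an ES value (frame 26)
chosen so the analytic volume curve attains the requested ejection
fraction; the myocardium is a fixed-thickness annulus; the RV is a crescent
adjacent to the LV. Defaults: ED endocardial radius 21 mm (analytic LVEDV
≈ 139 mL, inside the normal adult range), wall 8 mm, EF target 0.60,
tissue intensity levels 0.2 (background) / 0.5 (myocardium) / 0.9 (blood),
Gaussian blur 0.8 px and additive noise sd 0.05 — a modest contrast/noise
setting a cine bSSFP reader would call clean. Long-axis phantoms are
single-slice contracting ellipses with the 2-class (LA) and 3-class
(LA + RA) schemes. All randomness flows from one explicit seed; identical
seeds give bit-identical cases.

Deliberate simplifications: a single global radial scaling (no
through-plane motion, no twisting), no papillary muscles, no bSSFP banding
or coil shading, no pathology, and constant myocardial thickness over the
cycle (real myocardium thickens in systole, conserving volume). A green
test on the phantom therefore establishes that the *pipeline machinery* is
correct — geometry handling, learning dynamics, metric and measure
arithmetic, ED/ES logic — not that the network reaches published accuracy
on real cine CMR, which requires the original cohorts.

Simulated observers perturb structure boundaries with a smooth random
displacement field (a coarse Gaussian grid bilinearly upsampled, scaled to
a requested RMS amplitude in mm, applied by nearest-neighbour warping).
Smoothness preserves topology at realistic amplitudes; zero jitter is the
identity. This emulates inter-observer contour variability, not systematic
protocol differences between observers.

## Numerical choices

- **Metrics in physical units.** Contours are boundary pixels under
  4-connectivity (grid border counts as outside); distances are Euclidean
  between pixel centres in mm. Distances are computed in-plane per 2D slice
  — the natural reading when mean distances are compared against the
  in-plane pixel spacing — with the case MCD the mean and the case HD the
  maximum over contributing slices; Dice is pooled over the 3D voxel sets
  of annotated frames. Per-slice Dice and the alternative aggregation are
  available behind flags. Planes where a structure is empty in either map
  are excluded and counted, never scored 0 or 1.
- **Ties and degenerate inputs.** Argmax ties resolve to the lowest label
  index; both-empty Dice is flagged undefined (NA) and excluded from
  aggregates; max-pooling ties take the earliest position. Relative
  differences use the symmetric denominator (a+b)/2 — the upstream
  definition leaves the denominator open, and the symmetric choice avoids
  designating a reference observer — with a+b = 0 pairs excluded and
  counted.
- **ED/ES selection** is the argmax/argmin of the cavity volume curve with
  earliest-frame tie-breaking. Frame indices are 1-based throughout, the R
  convention. LV mass is evaluated at ED by default (the measurement frame
  is not prescribed upstream); the frame is configurable.
- **Limits of agreement** use the fixed 1.96 multiplier, not a
  t-correction.
- **No post-processing by default.** The method applies no morphological
  cleanup; an optional largest-connected-component filter exists but is
  off, so reported Hausdorff distances include any stray satellites.

## Known limitations

- Training at the full published scale (50,000 iterations, 192 × 192,
  batch 20) is possible but slow on CPU; the test suite exercises the
  training loop on reduced networks and grids. The implementation is exact,
  not approximate — only the problem sizes in tests are scaled down.
- The NIfTI-1 reader/writer covers the single-file `.nii`/`.nii.gz` subset
  with common datatypes and `scl_slope` rescaling; it does not implement
  extensions, `.hdr/.img` pairs, or full orientation (qform/sform)
  handling, and the package works in voxel space plus spacing only.
- Long-axis atrial volumes are voxel counts on the single slice, not
  area–length estimates; strain and wall thickness are out of scope.
- Configuration sidecars use JSON rather than YAML (no YAML parser is
  available in the dependency budget); the key structure is unchanged.
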