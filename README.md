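# cineseg

Automated analysis of cardiac cine MRI in R: a fully convolutional network
(FCN) for short-axis and long-axis segmentation, its complete training
procedure, the standard segmentation-agreement metrics, derivation of
clinical ventricular measures, and inter-observer agreement statistics — all
testable end to end on a bundled synthetic cine-phantom generator, so no
access-restricted imaging data is required.

## Who this is for

Researchers in cardiovascular image analysis who want a transparent,
dependency-light reference implementation of the standard cine-CMR analysis
pipeline: segment the left/right ventricle (LV/RV) and atria on cine stacks,
quantify chamber volumes and myocardial mass, and quantify agreement between
automated and human measurements. Everything — convolutions, batch
normalisation, transposed-convolution upsampling, backpropagation, Adam — is
implemented in this package (R + a small C++ kernel); there is no external
deep-learning runtime.

## The model

The network maps a `192 × 192` image slice to per-pixel class probabilities
over `K` label classes. Features are learned at five resolution scales
(sides 192/96/48/24/12), each scale a stack of `3 × 3` convolutions with
batch normalisation and ReLU, downsampled by a factor 2 after every two or
three convolutions. Each scale's feature map is upsampled back to full
resolution in a single transposed convolution, all scales are concatenated,
and a three-layer `1 × 1` convolutional head with a softmax predicts the
label map. The default (VGG-like) variant has 16 convolutional layers
excluding transposed convolutions; a residual variant replaces scales 3–5
with identity-skip residual blocks for 33 layers. Training minimises the
mean cross entropy between predicted probabilities and manual labels with
Adam (learning rate 0.001, 50,000 iterations, mini-batches of 20 slices)
under on-the-fly random translation/rotation/scaling/intensity augmentation.

Segmentation agreement is quantified by the Dice metric
`2|A∩B| / (|A|+|B|)`, the symmetric mean contour distance

    MCD = 1/(2|∂A|) Σ_{p∈∂A} d(p, ∂B) + 1/(2|∂B|) Σ_{q∈∂B} d(q, ∂A)

and the Hausdorff distance `max(max_p d(p,∂B), max_q d(q,∂A))`, in mm.
Chamber volumes are voxel counts times the volume per voxel; LV mass is
myocardial volume × 1.05 g/mL; stroke volume SV = EDV − ESV, ejection
fraction EF = 100·SV/EDV, cardiac output CO = SV × heart rate. Agreement of
measurements uses paired absolute/relative differences and Bland-Altman
bias ± 1.96 SD limits of agreement.

## Worked example

Generate a phantom, train a reduced network on noiseless cases, segment a
held-out case, and quantify it:

```r
library(cineseg)

p <- phantom_params(rows = 64, cols = 64, slices = 2, frames = 8,
                    spacing_mm = c(3.6, 3.6, 10), blur_sigma_px = 0,
                    noise_sd = 0, seed = 1)
case <- generate_phantom(p)
case
#> <phantom_case> short_axis, EF target 0.60, ED frame 1 (27.7 mL), ES frame 5 (11.1 mL)

net <- build_fcn(K = 4, variant = "vgg", scales = 2, widths = c(8, 16),
                 conv_counts = c(2, 2), head_widths = c(16, 16),
                 up_width = 8, input_size = 64, seed = 1)
r <- train(net, list(case),
           train_config(iterations = 300, batch_size = 8,
                        augment = FALSE, seed = 2))
seg <- segment_stack(r$net, case$stack)
evaluate_case(seg, case$truth)
#>       structure      dice    mcd_mm    hd_mm n_slices
#> 1     LV cavity 0.9377593 1.1490272  7.20000       16
#> 2 LV myocardium 0.9254902 0.5827286 10.18234       16
#> 3     RV cavity 0.9912184 0.3023639 29.02413       16

measures_report(case$truth)[c("LVEDV_mL", "LVESV_mL", "LVEF_pct")]
#> $LVEDV_mL
#> [1] 29.0304
#> $LVESV_mL
#> [1] 11.4048
#> $LVEF_pct
#> [1] 60.71429
```

The Dice values say the overfit reduced network recovers each structure's
voxel set to within a few percent of the truth; the mean contour distances
are below the 3.6 mm pixel spacing of this down-scaled phantom. The truth
segmentation's ejection fraction (60.7%) recovers the generative EF target
of 0.60 to within voxelisation error.

The same workflow is scriptable from the shell:

```sh
Rscript -e 'quit(status = cineseg::cineseg_cli())' phantom --out cases --n 4 --seed 1
Rscript -e 'quit(status = cineseg::cineseg_cli())' train --data cases --out net.rds --iterations 500
Rscript -e 'quit(status = cineseg::cineseg_cli())' segment --model net.rds --image cases/case_001_image.nii.gz --out seg.nii.gz
Rscript -e 'quit(status = cineseg::cineseg_cli())' evaluate --auto seg.nii.gz --manual cases/case_001_label.nii.gz --scheme sa --out metrics.csv
```

## Layout

- `R/` — implementation: NIfTI-1 I/O, preprocessing, phantom generator,
  network (+`src/` im2col/col2im kernels), training, inference, metrics,
  clinical measures, agreement statistics, CLI.
- `vignettes/cineseg-methods.Rmd` — the model, its assumptions, parameter
  choices, and what the phantom does and does not establish.
- `tests/testthat/` — unit, property and acceptance tests.
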