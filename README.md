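# mosaicdemix

Blind crosstalk removal for multiplex fluorescence images, with
mosaic-guided estimation that does not mistake biological colocalization
for spectral mixing.

## The problem

Fluorophore emission spectra overlap, so each channel of a multiplex
image contains a fraction of its neighbours' signal. For a channel pair
the measured images relate to the true ones by a linear mixing model

    Img1 = F1 + a12 * F2
    Img2 = F2 + a21 * F1

with unknown mixing ratios `a12`, `a21 >= 0`. Without reference spectra,
the ratios can be estimated *blindly* by scanning candidates `a` and
minimizing the normalized mutual information

    MI = 2 (H1 + H2 - H12) / (H1 + H2)

between one channel and the residual `Img_i - a * Img_j`: at the true
ratio the leaked copy is gone and the channels are least dependent.

The known failure mode of this idea is that mutual information cannot
tell spectral leakage from genuine colocalization — two markers on the
same cells produce exactly the dependence the minimization removes, so
whole-image estimation subtracts real biology ("overcorrection").
`mosaicdemix` implements the remedy: partition the image into tiles of
1–2 cell diameters, score each tile's inter-channel structural
similarity (SSIM), estimate the ratios only on the tiles below a low
percentile of similarity — regions where the only dependence left is
spectroscopic — and then demix the whole image. Multi-channel stacks are
handled by an iterative update matrix `P` (ones on the diagonal,
`-gamma * a_ij` off it) with per-pair tile selection at every round.

The package is aimed at anyone processing CODEX/CyCIF-style multiplex
microscopy who needs crosstalk removal without per-experiment spectral
calibration, and at methodologists studying the colocalization/crosstalk
confound: a synthetic phantom generator with known ground truth makes
every claim testable offline.

## Worked example

```r
library(mosaicdemix)

# A two-channel phantom: half the cells express both markers, the other
# half are single-positive; then apply known crosstalk (0.2, 0.6).
truth_alpha <- matrix(c(0, 0.6, 0.2, 0), 2, 2)
spec  <- phantom_spec(coloc_fraction = 0.5, true_alpha = truth_alpha,
                      seed = 7)
truth <- generate_ground_truth(spec)
mixed <- apply_mixing(truth, truth_alpha)

# Whole-image MI minimization is confounded by the colocalized half:
estimate_alpha(mixed[[1]], mixed[[2]])$argmin_alpha   # 0.78  (true: 0.2)
estimate_alpha(mixed[[2]], mixed[[1]])$argmin_alpha   # 0.81  (true: 0.6)

# Mosaic estimation on the 1st-percentile lowest-SSIM tiles recovers it:
mos <- mosaic_alpha(mixed[[1]], mixed[[2]])
mos$forward$argmin_alpha                              # 0.2
mos$reverse$argmin_alpha                              # 0.6

# Demix the stack with the mosaic selector:
res <- demix_stack(mixed, demix_config(), mosaic_selector())
res$estimate
#> <mixing_estimate> 2 channels, gamma = 1, iterations = 1
#>      [,1] [,2]
#> [1,]  0.0  0.2
#> [2,]  0.6  0.0
```

The whole-image estimates (0.78, 0.81) illustrate the overcorrection the
mosaic step exists to avoid: they would subtract most of the genuinely
shared signal. The mosaic estimates land on the simulated truth to grid
resolution, and the demixed stack matches the ground-truth channels up
to shot noise.

A command-line interface wraps the same pipeline
(`simulate`, `demix`, `qc`, `benchmark`):

```sh
Rscript inst/exec/mosaicdemix simulate --out phantom/ --coloc 0.5 \
        --a12 0.2 --a21 0.6 --seed 7
Rscript inst/exec/mosaicdemix demix --in phantom/mixed.tif \
        --out demixed.tif --mode mosaic
Rscript inst/exec/mosaicdemix qc --in phantom/mixed.tif --out qc/
```

`qc` writes a per-tile heterogeneity report (tile SSIM against
independently estimated per-tile ratios) — spatially heterogeneous
ratios are the tell-tale of overcorrection risk — and flags channel
pairs whose per-tile ratio spread is large.

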