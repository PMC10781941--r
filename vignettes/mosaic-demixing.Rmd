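---
title: "Mosaic-guided crosstalk removal: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic-guided crosstalk removal: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicdemix)
```

## The problem

Multiplex fluorescence imaging measures several molecular targets in the
same tissue section, one fluorophore per channel. Fluorophore emission
spectra overlap, so each measured channel contains a fraction of its
neighbours' signal. For a channel pair, the measured images relate to the
true ones through a linear mixing model:

$$\mathrm{Img}_1 = F_1 + \alpha_{12} F_2, \qquad
  \mathrm{Img}_2 = F_2 + \alpha_{21} F_1,$$

with dimensionless mixing ratios $\alpha_{ij} \ge 0$ (the fraction of
channel $j$'s true signal that leaks into measured channel $i$).
`mosaicdemix` estimates these ratios *blindly* — without reference
emission spectra — and inverts the model.

## Mutual-information minimization and its failure mode

The blind estimator scans candidate ratios $a$ and evaluates the
normalized mutual information

$$\mathrm{MI}_{1,2} = \frac{2\,(H_1 + H_2 - H_{1,2})}{H_1 + H_2}
  \in [0, 1]$$

between the source channel and the residual
$\mathrm{Img}_i - a\,\mathrm{Img}_j$ (clamped at zero, since fluorescence
is non-negative). At the true ratio the leaked copy has been removed and
the statistical dependence between the channels is smallest, so the MI
minimum identifies $\alpha_{ij}$.

The catch: mutual information cannot distinguish *spectral* mixing from
*biological* colocalization. Two markers expressed on the same cells
(e.g. two surface proteins of one cell population) produce exactly the
inter-channel dependence that MI minimization is built to remove.
Minimizing MI on such a pair subtracts genuinely colocalized signal —
overcorrection — and the demixed images portray colocalized targets as
mutually exclusive.

## The mosaic remedy

Tissue is spatially heterogeneous: even when two markers colocalize over
most of a section, there are regions where they separate. The mosaic
procedure exploits this. The image pair is partitioned into square tiles
of roughly one to two cell diameters, each tile is scored with the
structural similarity index (SSIM), and only the tiles below a low
percentile of the score distribution (default the 1st percentile) are
combined into a composite on which the ratios are estimated. In those
low-similarity regions the only inter-channel dependence left is the
spectroscopic one, so the MI minimum lands at the true ratio, which is
then applied to demix the *entire* image.

For stacks of three or more channels the procedure iterates: at round
$k$, ratios are estimated for every ordered pair on that pair's own
selected tiles of the current stack, assembled into the update matrix
$P^k$ ($P_{ii} = 1$, $P_{ij} = -\gamma\,\alpha_{ij}^k$), and the stack is
updated as $X^{k+1} = P^k X^k$ with negatives clamped, until the largest
per-round ratio drops below a tolerance.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bins` | 256 | Histogram bins for the entropy estimates. |
| `tile_size` | 64 px | Mosaic tile side; aim for 1–2 cell diameters (`tiles_for_cell_diameter()` converts). |
| `percentile` | 0.01 | Fraction of lowest-similarity tiles combined for estimation; small images need a larger value, and at least one tile is always kept. |
| `metric` | SSIM | Tile similarity score; normalized MI is available (`metric = "mi"`) but costs more. |
| `gamma` | 1 (n=2), 0.5 (n≥3) | Update step size; damped steps stabilize multi-channel coupling. |
| `max_iters` | 1 (n=2), 10 (n≥3) | Iteration cap. |
| `tol` | 0.01 | Convergence threshold on the largest per-round ratio. |
| `alpha_max` | 1 | Cap on individual ratios; capped estimates are flagged as suspect. |
| grid step | 0.01 | Spacing of the candidate-ratio grid on [0, 1]. |

The defaults were fixed while designing the estimator and generator and
are used unchanged by the test-suite and the acceptance script.

## Numerical choices

**Histogram binning.** Marginal and joint entropies are plug-in
estimates on 256-bin histograms, each image binned on its own min–max
range. Per-image binning makes the entropies invariant to affine
rescaling of a channel, which matters here: the residual's amplitude
shrinks as the candidate ratio grows, and binning it on a range fixed by
the brighter partner would deflate its entropy purely through that
shrinkage, dragging the MI minimum toward maximal subtraction. (A fixed
absolute range remains available through `hist_spec(range = )`.) Empty
bins contribute zero; logs are base 2.

**The plateau rule for the argmin.** Because the clamped subtraction
saturates once a leaked component is fully removed, the MI-versus-ratio
curve typically falls to a flat valley that extends from the true ratio
toward larger candidates, with only estimation noise inside the valley.
`estimate_alpha()` therefore returns the *smallest* candidate whose MI
lies within `max(0.05 × curve amplitude, 0.005)` of the minimum — the
least-correction principle: within the statistical resolution of the
curve, prefer the weakest correction that explains the data. The
absolute floor (0.005 NMI) means a curve that is flat to within
estimation noise yields zero: no measurable crosstalk, no correction. A
strict interior minimum is refined by one three-point parabolic fit.

**Clamping.** Negative intensities produced by subtraction are clamped
to zero both inside the MI evaluation and in final outputs. Clamping is
not cosmetic: it is what makes the estimator reproduce the documented
overcorrection behaviour on colocalized data, because subtraction then
genuinely erodes shared structure.

**Tile scoring.** SSIM uses a uniform 7×7 window, $K_1 = 0.01$,
$K_2 = 0.03$, sample ($n-1$) covariance normalization, averaged over all
full windows. When scoring tiles, one data range — the pair's global
max–min — is used for every tile, as when SSIM is evaluated on a
fixed-dtype image. Per-tile ranges would make structureless (noise-only)
tiles score spuriously low and dominate the low-percentile selection;
with a global range such tiles score as *similar* (both are empty),
which is the scientifically correct reading.

**Selection arithmetic.** Tiles at or below the empirical `percentile`
quantile (lower interpolation, boundary ties included) are selected,
with a floor of `max(1, ceiling(percentile × T))` tiles. Composites are
packed row-major into the most-square grid when tile sizes allow,
otherwise concatenated without padding; MI is histogram-based and
insensitive to the arrangement, and SSIM is never recomputed across tile
seams. Degenerate composites (a source with no structure) carry no
evidence of crosstalk and yield a ratio of zero rather than an error.

**Iteration order.** All pairwise ratios within a round are estimated
from the same stack snapshot and applied simultaneously through $P^k$
(Jacobi-style), matching the printed update rule; the update is applied
in the round that satisfies the tolerance, and a run that exhausts
`max_iters` returns with `converged = FALSE` rather than an exception.
The `estimate` returned by `demix_stack()` accumulates
$\sum_k \gamma A^k$ — the per-round corrections actually applied; the
exact effective linear map is the product of the $P^k$, reconstructible
from the returned history.

## What the synthetic phantoms emulate

`generate_ground_truth()` builds two- or n-channel fields of cell-like
Gaussian blobs (default: 80 cells per channel of radius 6 px on a
256×256 field — a dense, tissue-like packing; blob s.d. is radius/2.5 so
that halos fall below 1% of peak at the minimum centre separation of 2.5
radii and adjacent cells do not read as colocalized). A fraction `rho`
of blob centres is shared across channels with independently jittered
amplitudes — spatial colocalization without intensity identity, the
two-markers-on-one-cell scenario. The remaining, single-positive blobs
of all channels are interleaved in a disjoint zone (a bottom band sized
to hold them), mirroring the zonal organization of real tissue where
single-positive cells concentrate in distinct compartments. This zonal
structure is not incidental: low-similarity-region selection can only
work if the sample *has* dissimilar regions, which is precisely the
method's operating assumption for real tissue.

Noise is intensity-dependent shot noise (s.d. 2% of peak at full
intensity, zero on the dark background), emulating background-subtracted
cyclic-immunofluorescence data; additive read noise and Poisson
resampling are available. Crosstalk is applied afterwards by the exact
forward model (`apply_mixing()`), so colocalization and mixing — the two
effects the method must separate — are controlled independently.

What the phantoms do **not** model: point-spread-function optics,
autofluorescence texture, registration error across imaging cycles, and
tissue morphology beyond isotropic blobs. Passing tests on phantoms
therefore demonstrates the estimator's behaviour under controlled
colocalization and known mixing, not performance on any particular real
dataset.

## Problem sizes used by the tests

The test-suite and acceptance script run 256×256 two- and three-channel
phantoms, 10 replicates for recovery checks and 20 seeds for the
overcorrection/rescue contrast, with the default 0.01-step candidate
grid. These sizes were chosen as the smallest fields that hold a dense
cell population and a meaningful 4×4 tiling.

## Known limitations

- With 16 tiles, the 1st-percentile selection floors at a single tile;
  a warning recommends a larger percentile for small images.
- Ratios at the search cap (`alpha_max`) are reported but flagged; a
  capped estimate usually signals colocalization-driven overcorrection
  rather than genuine 100% crosstalk.
- The estimator assumes non-negative, background-subtracted input. A
  large additive background offset violates the mixing model (the model
  would mix the offsets too) and degrades the MI minimum.
- Per-tile independent estimates (`heterogeneity_report()`) are
  statistically unstable below ~32 px tiles; they are a QC surface, not
  precision estimates.
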