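# mxifseg

Weakly supervised instance cell segmentation for two-channel multiplexed
immunofluorescence (MxIF) images in R.

Cellular immunoprofiling needs every cell in a tissue image isolated as
its own object — boundary and all — before marker intensities can be
quantified per cell. In MxIF data the cells are densely packed, the
membrane stain (e.g. Na⁺K⁺ATPase, channel "MEM") is thin and frequently
broken, and manually contouring the ~200 cells of one 512 × 512 ROI takes
hours. `mxifseg` implements a pipeline built around two ideas:

1. **Weak labels from classical segmentation.** Nuclei are segmented on
   the DAPI channel by Otsu thresholding + seeded watershed on the
   distance transform; eroded nuclear instances then seed a
   marker-controlled watershed on the membrane channel, and regions
   ≥ 1400 px (large background areas) are filtered out. A human corrects
   residual errors through recorded *edit overlays* (split polylines,
   removal contours), and a trainable three-class
   (boundary/interior/background) segmenter is bootstrapped recursively
   over weak sets — e.g. sizes (26, 16, 168) give labelled pools
   (26, 42, 42) with 168 prediction-only outputs.
2. **Two-stage domain adaptation.** An instance-segmentation backend is
   fine-tuned first on the weak-label set, then on a small manually
   annotated set (heads for 20 epochs, all layers for 40; SGD, batch 6,
   lr 1e-4, gradients clipped to 5.0 for the heavy backend contract). A
   CPU reference backend (pixel MLP + connected components) exercises the
   protocol at desk scale.

Quality is measured at the object level with the size-weighted,
bidirectional **object-Dice**

OD(S, G) = ½ [ Σᵢ ωᵢ · Dice(Sᵢ, G<sub>match(i)</sub>) +
Σⱼ ω̃ⱼ · Dice(Gⱼ, S<sub>match(j)</sub>) ],  ωᵢ = |Sᵢ| / Σₖ|Sₖ|,

and the analogously weighted **object-Hausdorff** over matched boundary
pairs: merging two touching cells leaves pixel Dice perfect but lowers OD,
which is exactly the failure mode these metrics are for. A synthetic ROI
generator (packed Voronoi cells, one nucleus per cell, membrane ridges
with controllable breaks, 16-bit noise) provides exact ground truth for
every test.

## Worked example

```r
library(mxifseg)

# a synthetic 512x512 ROI: clean membranes, no noise
cfg <- synth_config(noise_sd = 0, membrane_break_probability = 0, seed = 3)
roi <- generate_roi(cfg)
roi
#> <SynthROI: 512 x 512, 256 cell(s), seed 3>

# classical weak-label pipeline
nuc  <- segment_nuclei_classic(roi$dapi)
weak <- generate_weak_labels(roi$dapi, roi$mem, nuc)
weak
#> <CellWeakLabels: 512 x 512, 256 cell(s)>

object_dice(weak$instances, roi$gt_cells)
#> [1] 0.9718208

# per-cell profiling on the DAPI channel
tab <- profile_cells(weak$instances, nuc$instances,
                     list(dapi = roi$dapi))
head(tab[, c("cell_id", "area_px", "area_um2", "mean_dapi", "nucleus_id")], 3)
#>   cell_id area_px area_um2 mean_dapi nucleus_id
#> 1       1     943 80.95561  7569.242          1
#> 2       2    1160 99.58484  5968.500          2
#> 3       3     992 85.16221  7217.122          3
```

All 256 ground-truth cells are recovered (one instance per cell containing
a nucleus) and the weak labels agree with ground truth at OD ≈ 0.97;
with membrane-break probability 0.2 and 0.5 the OD degrades monotonically
(≈ 0.93 and ≈ 0.88) — the failure mode that motivates learning-based
refinement. The areas column converts pixels to µm² at the native
0.293 µm/pixel.

The command line covers the same pipeline end to end:

```sh
Rscript inst/cli/mxifseg simulate  --out roi1 --seed 1
Rscript inst/cli/mxifseg weaklabel --roi roi1 --out weak1
Rscript inst/cli/mxifseg train     --manual roi1 --out backend.json
Rscript inst/cli/mxifseg segment   --model backend.json --roi roi1 --out pred/roi1.tif
Rscript inst/cli/mxifseg evaluate  --pred pred --truth truth --out report.csv
Rscript inst/cli/mxifseg profile   --cells pred/roi1.tif --nuclei weak1/nuclei.tif --out cells.csv
```

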