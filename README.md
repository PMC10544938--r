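# PanicleScan

Measure rice grain phenotypes directly on intact panicles from calibrated
flatbed-scanner images — no threshing, no grain-by-grain handling.

Grain number, length, width, projection area, perimeter and the shape
ratios derived from them are core yield and quality phenotypes. Scanning an
intact panicle and measuring on the image is fast and non-destructive, but
raises three problems this package addresses as a cascade:

1. **Detection** — find every grain on the panicle. A deterministic
   classical detector (Otsu segmentation of the red channel + watershed of
   the Euclidean distance transform, solidity scores, NMS at IoU 0.74)
   covers desk-scale work; a compact trainable two-stage detector with
   feature-pyramid fusion exposes the full method's configuration
   (1425×1700 input, 4000 proposals, SGD lr 0.02 / momentum 0.9 / weight
   decay 1e-4, 100 epochs) as a training contract.
2. **Occlusion restoration** — complete silhouettes hidden by neighbouring
   grains or the rachis. A geometric baseline fits an ellipse to the
   visible contour by direct least squares and fills the hidden region; a
   compact conditional GAN (U-Net generator with skip connections, fused
   global + patch discriminator, L1 + adversarial objective, 256×256,
   Adam lr 2e-4) implements the learned path.
3. **Measurement** — per grain: length is the farthest contour point pair,
   width the maximal chord perpendicular to that axis, area the silhouette
   pixel count, perimeter the simplified contour arc length, all converted
   to millimetres through the scanner resolution (`mm/px = 25.4 / dpi`;
   0.0423 mm at 600 dpi). Derived: length/width ratio, area/perimeter
   ratio, circularity `4πA/P²`, equivalent ellipse. Aggregation yields the
   fifteen panicle traits (GN plus mean/SD of the seven grain quantities)
   and thousand-grain distributions.

A first-class synthetic-scene generator (superellipse grains drawn from
the published population statistics, exact masks, boxes, trait truth and
occlusion ratios) makes every stage testable without any image downloads,
and the full evaluation-metric suite (R², MAPE, RMSE, PSNR, SSIM, AP/mAP)
is implemented and oracle-tested.

## Worked example

Simulate a panicle scene, run the cascade, and compare with the
generator's exact truth:

```r
library(PanicleScan)

sc  <- generateScene(80, occlusionMax = 0.2, seed = 42,
                     width = 900, height = 1000)
res <- runPipeline(list(sc$image), PipelineConfig(restorer = "baseline"))
round(res$panicles, 3)
#>   panicle_id GN  MGL   SGL   MGW   SGW   MGPA  SGPA    MGP   SGP MGAPR SGAPR
#> 1          1 76 8.88 0.922 2.988 0.757 20.414 4.428 20.484 2.773  0.99 0.092
#>     MGC   SGC MGLWR SGLWR
#> 1 0.613 0.062 3.059 0.469
```

76 of the 80 grains were detected (the remaining four are fused in
crossing overlaps); the panicle means sit next to the true population
values of this scene (true MGL 8.652 mm, true MGW 2.778 mm). The 15
columns are the standard panicle trait set: grain number, then mean/SD
pairs of grain length, width, projection area, perimeter, area/perimeter
ratio, circularity, and length/width ratio.

Single grains measure in physical units at the scan's resolution:

```r
g  <- sampleGrain(seed = 1)                    # 8.238 x 2.816 mm grain
r  <- renderGrain(g, mmPerPixel(600))
round(extractGrainTraits(r$pixels, mmPerPixel(600)), 3)
#>   length_mm width_mm area_mm2 perimeter_mm lw_ratio ap_ratio circularity
#> 1     8.289     2.87   19.607        19.53    2.888    1.004       0.646
#>   eq_minor_mm
#> 1       3.012
```

A thin CLI (`inst/scripts/grainscan`) wraps `simulate`, `detect`,
`extract`, `run` and `evaluate` for shell use.

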