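# vascq

Quantifying embryonic vascular volume growth from multi-sample
light-sheet time-lapses of zebrafish.

Long-term SPIM imaging of several embryos at once produces terabytes of
two-channel 3D stacks — an endothelial wall marker (*kdrl:EGFP*-style)
and a circulating red-blood-cell marker (*GATA1a:dsRed*-style) — split
into overlapping mosaic tiles per fish, angle and timepoint. `vascq`
implements the computational path from those tiles to growth curves and
fitted growth laws:

* **Mosaic planning** — how many overlapping acquisition volumes cover a
  growing embryo, and the resulting data rate.
* **Stitching** — phase-correlation registration initialised from stage
  positions, global least-squares placement, linear-blending fusion;
  registration on 2D maximum-intensity projections, applied to the 3D
  stacks.
* **Self-supervised 3D segmentation** — red blood cells circulate only
  inside perfused vessels, so a filtered/thresholded RBC channel is a
  free luminal ground truth. Six per-voxel features of the endothelial
  channel (raw, x/y/z gradients, gradient magnitude, inverse-gradient
  weighted raw) are combined by a linear model solved with the SVD
  pseudo-inverse on N = 5000 luminal/non-luminal sample points; the score
  image is thresholded with the Triangle algorithm and cleaned by a
  morphological opening.
* **ROI propagation** — a region drawn at the last timepoint is tracked
  backward by per-boundary-point normalized cross-correlation template
  matching (70 px templates in 140 px search windows) with median-of-7
  shift regularization.
* **Quantification** — isotropic nearest-neighbour resampling, voxel
  counting per annotation region, two-angle averaging, landmark-based
  temporal alignment.
* **Growth models** — scaled cumulative log-logistic
  `V = A + V_L / (1 + (t/α)^(−β))` and log-normal
  `V = A + V_L Φ((ln t − µ)/σ)` fitted by Levenberg–Marquardt with
  multi-start, compared by residual sum of squares against Gompertz,
  logistic, Weibull and Richards models; analytic growth rates `dV/dt`
  and closed-form peak-growth times.
* **Synthetic data** — tubular two-channel phantoms with ground-truth
  wall/lumen masks, tile sets with known offsets, and noisy growth
  series, so the whole pipeline is testable without raw imagery.

## Worked example

Segment a synthetic phantom and measure its volume:

```r
library(vascq)

ph  <- generateVesselPhantom(phantomSpec(shape = c(96, 96, 96), seed = 1))
ph
#> PhantomVolume 96 x 96 x 96: vessel 5.81%, lumen 2.60% of voxels

seg <- segmentVolume(ph@endothelial, ph@rbc, segmentationConfig(N = 5000, seed = 1))
seg$model
#> SegmentationModel
#>   weights:
#>        raw      gradX      gradY      gradZ    gradMag invGradRaw       bias
#>   0.211800   0.013590  -0.007494   0.005093  -0.110500   0.038540   0.111300
#>   score threshold: 0.1982

measureVolume(seg$mask)$volumeUm3
#> [1] 46596
```

The learned weights are what the self-supervision promises: dominated by
raw brightness, with a negative gradient-magnitude correction that
suppresses edges. Against the phantom's ground truth this mask reaches a
Dice coefficient of 0.95.

Fit growth models to a volume time-series (here simulated from the
log-logistic law, 100 points over 17–89 hpf, 0.5% noise):

```r
p      <- exampleGrowthParams("log_logistic")   # A, V_L, alpha = 33, beta = 3
series <- generateGrowthSeries(growthSeriesSpec("log_logistic", p,
            noiseSigma = 0.005 * p[["V_L"]], seed = 1))
cmp    <- compareModels(series, growthModelIds())
cmp$table
#>         model          rss converged nParams
#>  log_logistic 449220698816      TRUE       4
#>    log_normal 461771598660      TRUE       4
#>      gompertz 552122213052      TRUE       4
#>      richards 552124627228      TRUE       5
#>      logistic 686158435816      TRUE       4
#>       weibull 842178304414      TRUE       4

fit <- cmp$fits$log_logistic
fitParams(fit)
#>          A        V_L      alpha       beta
#> 2.0108e+06 1.4998e+07 3.3004e+01 2.9997e+00

peakGrowthTime("log_logistic", fitParams(fit))$time
#> [1] 26.19377
```

The two log-time models rank first, the generating parameters are
recovered to a fraction of a percent, and the fitted growth-rate peak
lands at ~26 hours post fertilization — the timing of maximal
whole-vasculature growth.

A thin command-line front end over the same functions lives in
`inst/cli/vascq.R` (subcommands `phantom`, `plan`, `stitch`, `segment`,
`quantify`, `fit`, `run`); `runPipeline()` drives a whole experiment
folder (see the vignette for the layout).

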