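# sheetquant

Quantitative image analysis of plasma-membrane sheets.

Membrane sheets — the basal plasma membrane left on glass after
sonication-unroofing a cell — let you image the distribution of membrane
proteins and lipid reporters face-on. A typical question: does a
tetraspanin such as CD9 associate with PIP2-rich membrane areas (mapped
by a fluorescent PH-domain reporter), and does a point mutation change
that association? `sheetquant` implements the analysis chain such
studies use, end to end, for epi-fluorescence (83.3 nm/px) and
two-color STED (25 nm/px) data:

* **ROI quantification** — mean intensity in a square ROI minus an
  off-membrane background ROI (`measure_roi()`), plus per-replicate
  normalization to a control construct with a 95% t-interval that flags
  significance when it excludes 100% (`normalize_to_control()`), and
  immunoprecipitation band ratios (`band_ratio()`).
* **Colocalization** — Pearson correlation of two channels in the ROI
  (`pearson_roi()`), validated by the Costes test: the reporter channel
  is scrambled in 4-px PSF-sized blocks, and PCCs whose Costes P-value
  falls below 0.95 are excluded (`costes_test()`,
  `filter_by_costes()`).
* **Retention assay** — retained reporter vs construct expression
  fitted through the origin, θ̂ = Σxy/Σx² (`fit_through_origin()`); θ
  compares constructs at matched expression.
* **STED nano-clusters** — 50% crosstalk correction, σ = 0.5 px blur,
  ImageJ-compatible prominence maxima detection (`find_maxima()`),
  5-px-disc center-of-mass sub-pixel refinement, 31×3 linescan Gaussian
  classification (R² > 0.7 *and* peak in the middle third, per
  linescan), nearest-neighbor distances in nm against a flipped-image
  random control, and a noise-tolerance sweep (`sted_nn()`,
  `tolerance_sweep()`).
* **Synthetic scenes** — a generator with known ground truth
  (PIP2-like domain field, affinity-weighted nano-cluster placement,
  pixel-integrated Gaussian PSFs, Poisson noise, spectral crosstalk)
  that makes every stage testable without microscope data
  (`simulate_scene()`).

`run_experiment()` chains the stages from a YAML/list configuration and
writes CSV tables plus a provenance record;
`inst/cli/sheetquant-cli.R` wraps the same entry points for the shell.

## Worked example

```r
library(sheetquant)

## a synthetic membrane sheet: high-affinity construct, directly fixed
sc  <- simulate_scene("epi", shape = c(128, 128), n_clusters = 120,
                      affinity = 2, seed = 17, condition = "directly_fixed")
roi <- square_roi(32, 32, 64)   # on the membrane
bg  <- square_roi(0, 0, 16)     # next to it

measure_roi(sc$images$gfp, roi, bg, sheet_id = "CD9_s01")
#> <roi_measurement CD9_s01> raw 43.59, background 20.25, corrected 23.34

pearson_roi(sc$images$gfp, sc$images$ph, roi, sheet_id = "CD9_s01")
#> <pcc_result CD9_s01> PCC(gfp, ph) = 0.5921 over 4096 px

costes_test(sc$images$gfp, sc$images$ph, roi, seed = 1, sheet_id = "CD9_s01")
#> <costes_result CD9_s01> PCC 0.5921, P = 1.000 (100/100 scrambles below),
#>   block 4 px: keep
```

The corrected mean is the construct's signal above background; the PCC
of 0.59 between construct and reporter channel reflects the affinity-2
placement, and all 100 block scrambles degrade it, so the Costes test
keeps the value (P = 1.00 ≥ 0.95).

```r
## retention assay: patched sheets across an expression range
xy <- t(sapply(1:10, function(s) {
  sc <- simulate_scene("epi", shape = c(128, 128), n_clusters = 40 + s * 15,
                       affinity = 2, seed = 100 + s, condition = "aGFP")
  c(measure_roi(sc$images$gfp, roi, bg)$mean_corrected,
    measure_roi(sc$images$ph,  roi, bg)$mean_corrected)
}))
fit_through_origin(xy[, 1], xy[, 2])
#> <origin_fit> theta = 3.075, R^2 = 0.971, n = 10
```

θ ≈ 3.1 is the retained reporter per unit expression; a zero-affinity
construct on the same scenes gives θ ≈ 1.6, so the high-affinity
construct retains more reporter at matched expression.

```r
## STED: are the two constructs in the same nano-clusters?
st <- simulate_scene("sted", shape = c(128, 128), n_clusters = 40,
                     shared_fraction = 0.7, seed = 23)
sted_nn(st$images$red, st$images$longred)
#> <nn_distance_set> tolerances 2/4: 19/344 reference maxima accepted,
#>   69 target maxima
#>   observed mean NN 96.5 nm, flipped control 132.6 nm
```

70% of the target clusters share centers with the reference channel,
and the observed mean nearest-neighbor distance (96.5 nm) falls clearly
below the flipped-image random control (132.6 nm);
`summary(tolerance_sweep(...))` shows the same ordering at every noise
tolerance setting.

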