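---
title: "Quantifying protein-lipid association on membrane sheets"
author: "sheetquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein-lipid association on membrane sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheetquant)
```

## The measurement problem

Tetraspanins such as CD9 organize the plasma membrane into
tetraspanin-enriched microdomains and concentrate in nano-clusters of
roughly 100 nm. Whether and how their very short intracellular segments
sense signaling lipids — in particular PI(4,5)P~2~ (PIP2) — is an open
question. Experimentally this is probed on *membrane sheets*: the basal
plasma membrane of a cell left on the coverslip after sonication
unroofing, imaged face-on with co-registered fluorescence channels (a
TMA-DPH membrane marker, a GFP-tagged construct, and an mCherry/RFP
PH-domain reporter whose distribution maps the PIP2-rich areas; 83.3 nm
pixels in epi-fluorescence, 25 nm in STED).

`sheetquant` implements the quantitative image analyses this kind of
study relies on:

1. **ROI intensity quantification** with off-membrane background
   subtraction (`measure_roi()`), and per-replicate normalization to a
   control construct with a t-based confidence interval
   (`normalize_to_control()`).
2. **Pearson colocalization** inside the ROI (`pearson_roi()`) validated
   by the **Costes block-scramble test** (`costes_test()`,
   `filter_by_costes()`).
3. The **antibody-patching retention assay**: retained reporter versus
   construct expression, fitted through the origin
   (`fit_through_origin()`).
4. **Immunoprecipitation band ratios** (`band_ratio()`).
5. The **two-color STED nano-cluster pipeline** (`sted_nn()`): crosstalk
   correction, Gaussian blur, prominence-based maxima detection,
   sub-pixel center-of-mass refinement, linescan Gaussian classification,
   and nearest-neighbor distances against a flipped-image control, with a
   noise-tolerance sweep (`tolerance_sweep()`).
6. A **synthetic scene generator** (`simulate_scene()`) providing ground
   truth for all of the above.

Because the microscopy data behind such studies are typically not
deposited, every stage is validated against synthetic scenes with known
ground truth rather than against archived images; the acceptance checks
are therefore property-based (oracle equality, calibration, closed
forms, qualitative orderings), not pixel-level reproductions.

## Models and procedures

### ROI quantification and normalization

Intensities are arithmetic means over a square ROI placed on a
hole-free membrane region, minus the mean of a background ROI placed
next to the membrane. Corrected means are *not* clipped at zero:
clipping would bias averages of near-background replicates upward. For
construct comparisons within a dye/labeling batch, each replicate's test
value is expressed as a percentage of the control construct in the same
replicate; the mean percentage carries a two-sided 95% t-interval with
n − 1 degrees of freedom, and the difference is called significant when
the interval excludes 100%. The 95% level is fixed; it is the
conventional choice when the source protocol states significance but not
a level.

### Colocalization and the Costes test

The Pearson coefficient over paired raw ROI pixels is 1 for perfect
overlap, 0 for unrelated images, −1 for an image and its negative; no
background subtraction enters (the PCC is invariant to positive affine
rescaling of either channel). Small average PCC differences are only
meaningful if each individual PCC exceeds chance, so each value is
validated by Costes block scrambling: the reporter channel is cut into
PSF-sized tiles (4 px at 83.3 nm/px), the tiles are permuted uniformly
at random (default 100 times), and the PCC is recomputed each time
against the unchanged first channel. The Costes P-value is the fraction
of scrambled PCCs *strictly* below the observed one — ties count
against keeping, which is conservative toward exclusion — and PCCs with
P < 0.95 are excluded. Two implementation decisions keep observed and
null on identical supports: the ROI is cropped to the largest multiple
of the block size before both computations, and only the reporter
channel is scrambled. With 100 scrambles the keep probability under
independence is 6/101 ≈ 5.9% (ranks are exchangeable and the P-value
takes 101 discrete values), so the expected exclusion rate is ≈ 94%,
slightly below the nominal 95%.

### Retention regression

In the patching assay, an anti-GFP antibody aggregates the GFP-tagged
construct before fixation; reporter molecules residing in the patched
domains are trapped and survive rinsing. Retained reporter intensity
*y* is regressed on construct expression *x* through the origin,
\(\hat\theta = \sum x_i y_i / \sum x_i^2\): a sheet expressing nothing
retains nothing, and \(\theta\) measures retained reporter per unit
expression, comparable across constructs at matched expression. The
reported R² uses the centered total sum of squares (the convention of
common plotting software, which can go negative for origin-forced
fits); the uncentered variant is also returned
(`r_squared_uncentered`) since the convention is ambiguous in the
field.

### STED nano-cluster analysis

The two STED channels (red: reference construct; long-red: target
construct) are processed as an ImageJ-macro-equivalent pipeline:

* **Crosstalk**: the long-red channel contains 50% bleed from the red
  dye; `correct_crosstalk()` subtracts `0.5 * red` and clips at zero
  (negative photon counts would destabilize the center of mass).
  Correction precedes blurring.
* **Blur**: isotropic Gaussian, σ = 0.5 px, separable convolution with
  reflective borders (mass-conserving for interior content).
* **Maxima**: `find_maxima()` re-specifies ImageJ's *Find maxima* as a
  deterministic prominence/flood contract: candidates are processed in
  descending intensity; each grows an 8-connected region over pixels
  within `noise_tolerance` of its peak; reaching higher terrain or a
  higher peak's territory before descending more than the tolerance
  merges the candidate away. Equal-valued plateaus count once, at the
  plateau pixel nearest the plateau centroid (lexicographic (row, col)
  tie-break). This contract is checked against an exhaustive
  per-candidate component-search oracle in the tests — exact set
  equality on random integer images.
* **Sub-pixel position**: intensity-weighted centroid over the 21
  pixels whose centers fall in a 5-px-diameter disc on the maximum.
  Note the truncated disc shrinks large sub-pixel offsets toward the
  pixel center (about half, for spots of σ ≈ 1.6 px); this is inherent
  to the disc center-of-mass estimator, unbiased over symmetric offsets
  (RMSE ≈ 0.16 px at 1500 photons on Poisson noise).
* **Classification**: two 31 × 3 px linescans (horizontal, vertical)
  averaged across their width; a 4-parameter Gaussian
  \(A e^{-(x-\mu)^2/2\sigma^2} + b\) is fitted by Levenberg–Marquardt
  (start: b = min, A = max − min, μ = argmax, σ = 2 px; σ bounded to
  [0.5, 31] px; failed fits get R² = −∞). A maximum is a nano-cluster
  if *at least one* linescan has R² > 0.7 *and* its fitted peak in the
  middle third of the scan (μ ∈ [31/3, 62/3], 0-based) — the
  conjunction is per-linescan. The middle-third rule does real work: a
  Gaussian *flank* can track a linear ramp with R² near 1, but its
  fitted peak always lands outside the middle third, so ramps and edge
  artifacts are rejected.
* **Distances**: for each accepted reference cluster, the Euclidean
  distance (nm) to the nearest target-channel maximum, both at
  sub-pixel positions (target refinement can be disabled with
  `refine_targets = FALSE`, since protocols are ambiguous on this
  point). The random-distance control recomputes the distances after
  mirroring the target positions left-right across the image midline
  (`flip_control()`; the mirror axis is configurable — for spatially
  independent channels the choice does not matter in expectation).
  Only reference maxima are classified; target maxima are not.
* **Sweep**: the analysis is repeated over tolerance pairs
  (2, 4), (4, 8), (6, 12), (2, 12). Larger tolerances keep fewer maxima
  and lengthen shortest distances; a robust biological conclusion
  should not flip across settings. Candidates whose disc or linescan
  window would leave the image are excluded before classification to
  avoid biased truncated fits.

Under complete spatial randomness of the target maxima at intensity λ
per nm², the mean nearest-neighbor distance is \(1/(2\sqrt{\lambda})\);
the implementation reproduces this closed form to well under 2% at
10^4^ points, and for statistically independent channels the observed
and flipped means agree within sampling error.

## The synthetic scene generator

`simulate_scene()` emulates exactly the features the analyses depend
on, with ground truth stored alongside the images:

* **Domain field** (`generate_domain_field()`): Gaussian-smoothed white
  noise through a soft logistic threshold, normalized to mean 1 — a
  smooth field with contiguous "rich areas" covering a chosen fraction
  (default 30%) of the membrane, standing in for the PH-reported PIP2
  pattern. The smoothing bandwidth is half the correlation length, so
  the pre-threshold autocorrelation reaches 1/e at the stated
  correlation length (defaults: 6 px epi ≈ 0.5 µm, 20 px STED).
* **Nano-clusters** (`place_emitters()`): cluster centers drawn with
  probability ∝ domain^affinity^ — affinity 0 is complete spatial
  randomness, larger values model constructs preferring PIP2-rich
  areas. Centers are continuous (sub-pixel); copies per cluster are
  shifted Poisson (min 1, mean 4).
* **Rendering** (`render_channel()`): pixel-integrated isotropic
  Gaussian spots (flux-exact for interior spots) over a constant
  background, then Poisson shot noise. PSF widths default to σ 110 nm
  (epi) and 40 nm (STED); 300 and 1000 expected photons per copy.
* **Epi scenes** add a central membrane footprint (15% margin per edge)
  with only camera background outside, so background ROIs "next to the
  membrane" behave as in the real assay. The reporter channel is
  `ph_gain × domain` inside the membrane when directly fixed; under the
  patching condition only a 5% residual of the free reporter survives
  the rinse, plus reporter trapped under each cluster in proportion to
  the local domain value (1 trapped photon per construct photon by
  default) — this is what makes the retention slope θ increase with
  placement affinity.
* **STED scenes** render two clustered channels and mix 50% of the red
  channel into the long-red one (the artifact `correct_crosstalk()`
  removes); a chosen fraction of target cluster centers coincides with
  reference centers to emulate mixed nano-clusters.

The source protocol states no density or brightness statistics for its
images, so these defaults were chosen once for realism and testability:
cluster counts give maxima densities whose flipped-control distances
land in the 100–200 nm range, the same order as reported random
distances, and photon counts give single-cluster signal-to-background
around 10.

What the generator does **not** emulate: membrane topography or
TMA-DPH texture (the membrane channel is flat), photobleaching, drift,
detector read noise, 3D PSFs, or spatial copy spread within a cluster
(copies sit at the cluster center; at the epi PSF scale this is
irrelevant, at STED scale it makes synthetic clusters slightly more
point-like than real ~100 nm ones). Passing tests therefore demonstrate
correctness of the *analysis* under controlled conditions, not
photorealism of the simulation.

## Numerical choices and degenerate inputs

* Zero-variance ROIs raise a classed error
  (`sheetquant_zero_variance`) rather than silently returning NA.
* Candidates too close to the border for the disc or linescan raise
  `sheetquant_candidate_excluded`; the pipeline catches these and
  marks the candidate excluded.
* An all-zero disc falls back to the integer pixel position with a
  warning.
* A flat ROI yields zero maxima (an image-wide plateau has no
  prominence); `fit_through_origin()` refuses all-zero x; group
  summaries with zero within-group variance warn about exact
  separation.
* All stochastic steps take explicit seeds; scenes regenerate
  bit-identically, and `run_experiment()` writes every seed into its
  provenance record so identical configurations reproduce identical
  CSVs.

## Problem sizes used in the checks

The shipped verification suite runs entirely on synthetic data:
64–256 px scenes, 100–200 simulated ROIs or spots per calibration, 100
seeds per slope-recovery condition, 10 sheets per construct in the
end-to-end experiment, and 3 scenes per STED condition. These sizes put
Monte-Carlo noise comfortably below every asserted tolerance while the
whole suite completes in a couple of minutes.

## Limitations

ROI placement is caller-supplied (placement was manual in the source
protocol); there is no automatic membrane segmentation from the marker
channel, no Manders coefficients or Costes auto-thresholding, no gel
densitometry (band intensities are tabular input), and no cluster-size
estimation. The Costes scramble count (100) is a reproducibility
default, not a protocol value; raise `n_scrambles` for finer P-value
resolution.
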