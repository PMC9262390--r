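---
title: "Quantifying cortical polarity and spindle orientation in mitotic domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical polarity and spindle orientation in mitotic domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlepol)
```

## The measurement problem

In epithelia that orient cell divisions along a body axis, the evidence
chain runs through three quantities measured on 2D microscopy of mitotic
cells: (i) the angular position and strength of a cortical crescent of a
polarity protein (Pins/LGN) along the cell perimeter, (ii) the orientation
of the mitotic spindle relative to the anterior-posterior (AP) axis and how
it rotates toward its final angle, and (iii) the interphase cell shape, to
exclude the default explanation that cells simply divide along their long
axis (Hertwig's rule). `spindlepol` implements these three measurements,
the small-sample inference used to compare them across embryos, and a
synthetic data generator that provides ground truth for validating every
stage.

## Conventions

All images are en-face views with anterior at the top: row 1 of an image
matrix is the anterior edge and the AP axis is the image vertical. Directed
angles are measured from the anterior direction, positive counterclockwise
in this anterior-up view, in (-180, 180]. Spindle axes are undirected, so
axis angles live in (-90, 90]; the folded angle |signed| in [0, 90] is used
for reporting (0 = AP-aligned, 90 = DV-aligned). Perimeter traces start at
the anterior-most contour vertex and run clockwise for cells in the left
half of a mirrored domain and counterclockwise for the right half, so the
arclength coordinate of mirror-image cells is directly comparable. These
sign/direction choices are conventions, fixed and documented here because
published analyses typically report mirrored ranges without defining a
sign.

## Cortical profiles and the peak-to-trough ratio

`sample_perimeter_intensity()` samples a traced polygon at about one point
per pixel of boundary length; each sample is the mean over a transect of
configurable width (default 2 px) perpendicular to the boundary, using
bilinear interpolation, after an optional Gaussian pre-smoothing of the
image (0.75 px kernel — the standard figure-processing filter, applied so
measured and displayed data agree). Profiles are normalized to the mean
cytoplasmic gray value (`normalize_profile()`; renormalizing an
already-normalized profile rescales the normalized curve, so a second pass
with cytoplasm mean 1 is the identity), resampled onto a common circular
arclength grid by linear interpolation (`resample_profile()`), and averaged
hierarchically (`average_profiles()`): cells within an embryo first, then
embryos with equal weight, so an embryo with more traced cells does not
dominate the grand mean.

The per-cell polarity statistic (`peak_to_trough_ratio()`) smooths the
circular profile with a 5-sample moving mean, takes the global maximum, and
walks in both circular directions to the nearest local minima — the
"adjacent troughs". The ratio is peak over mean trough, with both values
read from the smoothed curve for internal consistency. Two edge cases are
fixed by design: a constant profile has ratio exactly 1 and carries a
`no_peak` flag (so control channels aggregate cleanly while remaining
distinguishable), and if only one distinct local minimum exists it serves
as both troughs (a dense sampling of `2 + cos(phi)` therefore gives ratio
exactly 3). Plateau ties at the maximum resolve to the circular midpoint of
the plateau. All statistics are invariant to the profile's start index.

## Division angles and rotation

`detect_poles()` finds the two spindle poles inside a contour: the frame is
Gaussian-smoothed, masked to the contour dilated by 2 px (so poles grazing
the cell boundary are not clipped), local maxima above a relative threshold
are collected, and the two strongest are refined to sub-pixel positions by
a 3-point parabolic fit on log intensity — exact for a Gaussian spot and
insensitive to signal from neighboring cells, with a windowed
intensity-weighted centroid as fallback. Pixels on the mask rim are never
extrema candidates, since they sit on a gradient by construction.

`track_rotation()` unwraps consecutive-frame axis angles with the
shorter-path rule on the 180°-periodic axis circle, takes the angle at the
declared anaphase frame as final (anaphase is an input, matching the
morphology-based staging of manual analyses — the package does not detect
anaphase), and classifies rotation direction by the sign of the net
displacement from the first frame to anaphase; |net| < 1° is "none". Net
displacement, rather than a frame-by-frame vote, is one defensible reading
of how wobbling spindles should be classified; it is the documented one.
Rose histograms (`rose_histogram()`) report the percentage of spindles per
bin (default 15° on [0, 90], configurable); bins are right-open with the
90° edge closed into the last bin.

## Shape fits and the long-axis rule

`fit_ellipse()` matches region-based "Fit Ellipse" semantics: the ellipse
with the same area and second central area moments as the filled polygon,
computed from the exact polygon-moment formulas rather than a
boundary-point least-squares fit, because that is what the standard
measurement tool reports. For an ellipse the covariance eigenvalues are
(a/2)² and (b/2)², so the axes are four times the square roots of the
eigenvalues and the aspect ratio is their square-rooted ratio. Near-circular
cells (AR < 1.02) are flagged `unreliable_axis` since their orientation is
ill-defined. `long_axis_rule_test()` correlates interphase long-axis angles
with division angles; because it is unstated in published analyses whether
angles are folded before correlating, both the folded and the signed
correlation are returned, labeled.

## Inference

Per-embryo mean angles are the units of between-group comparison, and with
3–10 embryos per group the normal approximation to the Mann-Whitney null is
poor, so `mann_whitney()` computes the exact null distribution of U by the
count recursion whenever there are no ties and both samples have at most 20
observations. The two-sided p-value is twice the smaller tail, capped at 1
— under complete separation this reproduces the minimal attainable value
`2 / choose(n1 + n2, n1)`. Larger or tied samples use the normal
approximation with continuity and tie correction. `spearman_cor()` likewise
enumerates all permutations for n ≤ 9 without ties and otherwise uses the
t-approximation with n − 2 degrees of freedom. Both exact paths are tested
against brute-force enumeration oracles, and both tests are verified to
hold their nominal 5% level by simulation under continuous nulls.

## The synthetic generator

`synth_config()` + `generate_domain()` emulate the statistical structure of
a head mitotic domain, not its mechanics: two mirrored elliptical clusters
of cells on a jittered hexagonal lattice (simpler than a Voronoi tissue and
sufficient for validating measurement code), a uniform cortical membrane
channel, and a polarity channel whose cortical intensity follows a
von-Mises-shaped modulation

  I(phi) = base · (1 + a · exp(kappa · (cos(phi − phi_c) − 1)))

— a smooth, single-peaked, closed-form crescent; real crescents have no
published functional form, so a canonical circular bump was chosen. Default
parameters are round numbers in the regime of confocal imaging of
gastrulating embryos: 40 cells per cluster (the largest head domain), 0.2
µm/px, cortex 200 a.u. over cytoplasm 50 a.u., contrast a = 1 and
kappa = 4 (a crescent of ~70° half-maximum width), crescent angle mean ±20°
per side (mirror symmetry; posterior-pointing directed crescents near ±160°
give identical axis statistics), 10° SD of crescent angle between cells,
and a final division angle equal to the crescent angle plus 10° of coupling
noise wrapped to the axis range. Spindles assemble at a uniformly random
angle and rotate toward the final angle along the shorter arc at a constant
10°/frame (the kinematic law is unspecified in the literature; constant
rate is the simplest monotone choice), freezing at the anaphase frame.
Imaging corruption is an isotropic Gaussian PSF followed by optional
Poisson shot noise and additive Gaussian read noise. A documented switch
(`double_sided_crescent`) renders the crescent on both sides of the cell,
since the imaging this emulates cannot resolve sidedness; single-sided is
the default.

Boundaries are rendered as an anti-aliased band (half-width 1 px,
supersampled coverage) rather than a rasterized line: line rasterization
produces a few-percent angular ripple that is larger than the crescent
modulation near its flat top and would corrupt peak-angle recovery. One
root seed drives everything through deterministic per-cell substreams, so
identical configurations are bit-reproducible and adding cells does not
reshuffle existing ones.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify on real data: curved 3D epithelium projected to 2D,
cell-cell junction signal shared between neighbors, intercalation and
other cell rearrangements, bleaching, depth-dependent attenuation, and
segmentation error in manual traces. The generator validates the
measurement code, not the biology.

## Validation scale and numerical choices

The test suite validates: crescent-angle recovery within 5° (mean) on
noisy image-free profiles (3 embryos × 10 cells, noise 5% of cortical
base — the study scale for intensity profiling) and on rendered fixtures;
final division angles within 2° and rotation chirality 100% correct (for
rotations ≥ 5°) on a noise-free rendered 100-cell cohort; ellipse aspect
ratios within 1% and orientations within 1° on analytic ellipse polygons;
exact-test equivalence to enumeration oracles for all Mann-Whitney splits
with n1 + n2 ≤ 12 and Spearman n ≤ 7; 5%-level calibration of all three
tests at 2000 null replicates; and reflection symmetry of the signed-angle
distributions of a 2000-cell mirrored cohort. Pipeline smoke tests run a
deliberately small configuration (two embryos of 8 cells at 224 px) to
stay fast; the defaults (`pipeline_config()`) use three embryos of 20
cells at 256 px.

Numerical details fixed by design: angular positions are measured about
the polygon centroid; ties at the circular wrap resolve toward 0;
perimeter sampling is ~1 sample per pixel of arc; bilinear interpolation
throughout; rose percentages always sum to 100 by construction; the
spindle renderer refuses configurations whose pole separation exceeds the
cell radius; `anaphase_frame` should satisfy
`rotation_rate · (anaphase_frame − 1) ≥ 90°` so any rotation can complete.

## Limitations

Angles are planar; out-of-plane spindle tilt is invisible and will shorten
apparent pole separations. Pole detection assumes exactly one spindle per
contour and two resolvable poles — in very dense tissue with spindles
pointing at each other across a shared boundary, resolution genuinely
fails and detection errors are raised rather than guessed around. The
peak-to-trough statistic assumes a single dominant crescent; bipolar
distributions are reported via their global maximum only. No multiple
testing correction is applied anywhere, matching the analysis style this
package reproduces.
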