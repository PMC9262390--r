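# spindlepol

Quantification of planar-polarized cortical proteins and mitotic spindle
orientation in epithelial mitotic domains.

During epithelial morphogenesis, groups of cells that divide synchronously
(mitotic domains) often orient their divisions along a body axis. A common
mechanism is a planar-polarized cortical crescent of the spindle-orientation
adaptor Pins/LGN, toward which the mitotic spindle rotates before anaphase.
`spindlepol` implements the measurement side of that biology for 2D
(en-face) microscopy:

- **Cortical intensity profiles.** Intensity is sampled along a traced cell
  perimeter (transect of width 2 px perpendicular to the boundary, after a
  0.75 px Gaussian smoothing), traced clockwise for cells in the left half
  of a mirrored domain and counterclockwise for the right half, normalized
  to the mean cytoplasmic gray value, resampled to a common circular grid,
  and averaged per cell, per embryo, and across embryos with equal embryo
  weights.
- **Polarity statistics.** For each cell, the angle of maximum cortical
  intensity `phi_max` and the peak-to-trough ratio
  `P = I(phi_max) / mean(I(trough_1), I(trough_2))`, where the troughs are
  the nearest circular local minima flanking the global maximum. `P ~ 1`
  for an unpolarized membrane marker and grows with crescent contrast.
- **Division angles.** Spindle poles are detected as the two strongest
  smoothed local maxima inside the cell contour (sub-pixel refinement by a
  log-parabolic fit). The division angle is the undirected angle between
  the pole-pole axis and the anterior-posterior (AP) axis, signed in
  (-90, 90] (positive = counterclockwise in the anterior-up view) and
  folded to [0, 90] for reporting (0 = AP-aligned, 90 = DV-aligned).
  Rotation direction (cw/ccw/none) is the sign of the net shorter-path
  angular displacement from spindle assembly to anaphase. Distributions are
  summarized as rose histograms (percent of spindles per angular bin) and
  per-embryo mean angles.
- **Shape and the long-axis rule.** Moment-equivalent ellipses (same area
  and second central moments as the filled polygon, exact polygon-moment
  formulas) give the interphase aspect ratio and long-axis angle, which are
  correlated against division angles to test Hertwig's rule.
- **Inference.** Two-sample Mann-Whitney with exact enumeration of the null
  distribution for small tie-free samples (the regime of per-embryo
  comparisons; under complete separation the two-sided p-value is
  `2 / choose(n1 + n2, n1)`), Spearman correlation with exact permutation
  p-values at small n, Pearson r / R², circular means, and grouped
  mean ± SD at the cell and embryo level.
- **Synthetic mitotic domains.** A generator builds two mirrored clusters
  of polygonal cells with a von-Mises-shaped cortical crescent
  `I(phi) = base * (1 + a * exp(kappa * (cos(phi - phi_c) - 1)))`, a
  uniform membrane channel, and a spindle time-lapse whose final angle is
  coupled to the crescent angle — with a per-cell ground-truth table, so
  every measurement stage can be validated by parameter recovery.

## Worked example

```r
library(spindlepol)

cfg <- synth_config(n_cells_per_side = 10, image_size = 256,
                    pole_separation = 3, gaussian_sd = 2, seed = 1)
domain <- generate_domain(cfg)
img <- render_polarity_image(domain, cfg)

ct <- cell_contour(domain$cells[[1]]$mitotic,
                   cell_id = domain$cells[[1]]$cell_id, side = "left")
prof <- sample_perimeter_intensity(img, ct, line_width = 2)
prof <- resample_profile(orient_profile(
  normalize_profile(prof, cfg$cytoplasm_intensity)), 128)
peak_to_trough_ratio(prof)
#> Polarity measurement: cell embryo1_l_c001 (unknown), P = 1.826, peak angle = 30.1 deg
domain$truth$true_crescent_angle[1]
#> [1] 30.7
```

The measured peak angle (30.1°) recovers the cell's true crescent angle
(30.7°), and `P = 1.83` reflects the generated contrast (`a = 1` would give
2 without the optical blur and cytoplasmic mixing).

Exact small-sample inference:

```r
mann_whitney(1:5, 6:10)
#> Two-sample Mann-Whitney (exact)
#>   U = 0, n1 = 5, n2 = 5, two-sided p = 0.00793651
```

The full pipeline (3 embryos, both channels, spindle tracking, shape fits,
statistics, plots):

```r
res <- run_pipeline(pipeline_config(), out_dir = "demo_out")
res$contrast$cell_summary
#>      group  n     mean         sd sd_undefined
#> 1  control 30 1.122081 0.08591594        FALSE
#> 2 polarity 30 1.875726 0.06202465        FALSE
```

In this run the polarity-vs-membrane contrast is significant
(Mann-Whitney p = 3.0e-11 over 30 + 30 cells), the angle of maximum
intensity predicts the division angle (Spearman rho = 0.61, p = 3.4e-4),
the long-axis rule is rejected (rho = -0.14, p = 0.30), and per-embryo mean
folded angles sit near the generating 20° tilt (22.7°, 17.0°, 23.2°).
`demo_out/` receives the ground truth, profile, polarity, division and
shape tables as CSV, rose and mean-profile plots, the configuration and a
run log.

## Scope

Contours come from the synthetic generator or from user tracing (CSV);
the package does not segment cells, measure 3D spindle angles, or model
tissue mechanics. See the vignette (`vignettes/quantifying-spindle-polarity.Rmd`)
for the measurement model, parameter choices and limitations.
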