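# morphodyn

Integrated analysis of 3D cell shape and movement in moving frames.

Migrating cells deform as they move, and the two processes share their
machinery: protrusions push the cell forward, and turning reorients the
protrusions. `morphodyn` quantifies both at once from a time series of
closed genus-0 triangular surface meshes (e.g. segmented 3D microscopy
of neutrophils). Its core idea is to describe every shape in a
coordinate frame that *travels with the cell and points along its
velocity*, so that the shape descriptor itself carries the
shape–movement coupling and is independent of how the scene was
oriented.

For one cell with positions r(t) (mass centers, smoothed by a zero-mean
Gaussian process with squared-exponential kernel
k(t,t′) = v·exp(−(t−t′)²/2ℓ²)), the package builds parallel-transport
moving frames (T, N, B): T is the unit velocity, N is carried along the
curve with minimal twist — if U = Tᵢ × Tᵢ₊₁ is nonzero, N is rotated
about U by θ = arccos(Tᵢ·Tᵢ₊₁), otherwise copied — and B = T × N. Each
mesh is mapped into its frame (v* = M(v − o), rows of M are T, N, B),
normalized to unit volume, parameterized on the unit sphere by
conformalized mean-curvature flow with first-order parameter
normalization, and expanded in orthonormal real spherical harmonics up
to degree l_max = 6, indexed j = l² + l + m + 1. The concatenated
coefficients C = (C_x, C_y, C_z) are the shape descriptor. From them:

- eccentricity indices E_xy = |C_x(1,1)|/|C_y(1,0)|,
  E_xz = |C_x(1,1)|/|C_z(1,−1)| (1 for a sphere; equal to the axis
  ratios for ellipsoids, with x the direction of motion),
- the shape-change rate d(t, t+1) = ‖C(t) − C(t+1)‖₂,
- and trajectory speed, curvature κ = |r′×r″|/|r′|³ and torsion
  τ = (r′×r″)·r‴/|r′×r″|².

Per cell these are aggregated into 26 features (median, MAD, 25th/75th
percentile of speed, curvature, torsion, shape-change rate, E_xy, E_xz,
plus curvature and torsion peak counts) for correlation analysis, 2D
embedding, KNN classification and permutation importance. A synthetic
moving-cell generator with full ground truth (trajectory, speed
profile, protrusion law) makes every stage testable.

## Worked example

```r
library(morphodyn)

# simulated moving cell: 250 true time points, 26 observed meshes,
# two-bump speed profile, pseudopod locked to the velocity
ds  <- generate_dataset(synthetic_cell_config(subdivisions = 2))
fit <- fit_cell(ds$meshes)   # full pipeline, moving-frame basis
fit
#> cell_fit 'cell' (moving basis): 26 time points, l_max = 6
#>   median speed 0.634, median E_xy 1.16, median E_xz 1.16

evaluate_trajectory_mse(fit$smooth, ds$truth)$mse_point
#> [1] 0.00185
round(fit$features[c("speed_median", "E_xy_median", "E_xz_median")], 3)
#>  speed_median  E_xy_median  E_xz_median
#>         0.634        1.162        1.159
```

The cell travels at a median 0.63 cell radii per frame; the smoothed
trajectory reconstructs the 250-point ground truth with mean squared
error 0.0019 (squared length units per time point); and in the moving
frame the cell is elongated *along its own direction of motion*
(median E_xy and E_xz ≈ 1.16 > 1), tracking the speed profile —
exactly the velocity-locked pseudopod the generator built in.
`plot(fit)` draws the speed/curvature/torsion and eccentricity time
courses; `coef(fit)` returns the 26 × 147 descriptor matrix;
`run_cohort()` compares moving-frame against standard-basis features
across cells (Kendall correlations, embedding, paired KNN
cross-validation, permutation importance).

A thin command-line wrapper with `simulate`, `run-cell` and
`run-cohort` subcommands is installed at `inst/cli/morphodyn.R`.

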