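---
title: "Joint shape-movement analysis of 3D cells in moving frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint shape-movement analysis of 3D cells in moving frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodyn)
```

## The problem

A migrating cell changes shape and position at the same time, and the two
processes are mechanically coupled: protrusion drives motion, motion
reorients protrusion. Quantifying them separately discards that coupling.
`morphodyn` analyses a time series of closed genus-0 triangle meshes (one
surface per time point, e.g. segmented two-photon stacks of neutrophils
in collagen) by describing every shape *in a coordinate frame that
travels with the cell and points along its velocity*. When the cell turns
or accelerates, the frame turns with it, so the shape descriptor itself
becomes sensitive to the shape-movement relationship, while remaining
invariant to how the scene happened to be oriented under the microscope.

The pipeline is: mass-center trajectory → Gaussian-process smoothing →
parallel-transport moving frames → per-time-point mesh reorientation →
volume normalization → mean-curvature-flow spherical parameterization →
real spherical-harmonic (SH) expansion → shape-movement features →
cohort statistics. `fit_cell()` runs all of it for one cell and returns a
fitted-model-style object; `run_cohort()` adds the statistical battery.

## Trajectory model

The cell position at time $t$ is the unweighted arithmetic mean of the
mesh vertices (not the volumetric centroid; a `method` switch on
`mass_center()` offers the latter). Each coordinate sequence is
standardized to zero mean and unit population standard deviation and
modelled as $s(t) = f(t) + \varepsilon$, with $f$ a zero-mean Gaussian
process with squared-exponential kernel
$k(t,t') = v\,e^{-(t-t')^2/(2\ell^2)}$ and
$\varepsilon \sim N(0, \sigma^2)$. The posterior mean is evaluated on a
dense grid (default `interpolation_factor = 10` subintervals per
sampling interval) and destandardized.

Parameter choices and their reasons:

* $\ell = e^{1.0}$, $v = 1$ (defaults of `gp_config()`), with **time
  rescaled by the median sampling interval** before fitting. The length
  scale is therefore "about 2.7 samples". On the raw time axis of the
  default simulation (observations every 10 frames) a length scale of
  2.7 frames would make consecutive observations nearly independent and
  the posterior mean would collapse to the prior between them;
  interval units are the only reading under which this kernel smooths
  rather than erases. `time_scale = "none"` restores raw units.
* $\sigma^2$ is not prescribed; by default it is chosen by maximizing
  the summed marginal likelihood of the three axes with $(\ell, v)$
  fixed, yielding **one shared noise variance**. Two design details
  matter here. A shared $\sigma^2$ makes the smoother an identical
  linear operator on every axis, so smoothing commutes exactly with
  rotations and translations of the scene. And the likelihood is
  evaluated on the centered sequences scaled by one *common* factor
  (root-mean per-axis variance), which makes the estimate itself a
  function of rotation-invariant quantities. Together these give exact
  rigid-motion equivariance of the smoothed trajectory — the anchor of
  the rotation-invariance property below. A fixed numeric
  `noise_variance` overrides the optimization.
* Constant (degenerate) axes are detected during standardization and
  carried through unchanged.

Speed, curvature and torsion come from central finite differences on the
dense grid: $\mathrm{speed}=|r'|$, $\kappa = |r'\times r''|/|r'|^3$,
$\tau = (r'\times r'')\cdot r''' / |r'\times r''|^2$. Torsion is
reported `NA` where $|r'\times r''| < 10^{-8}|r'|^3$ — on near-straight
segments torsion is not identifiable and finite differences there
produce pure noise. Consumers should additionally condition torsion
summaries on appreciable curvature, as the acceptance checks do.

## Parallel-transport moving frames

The tangent $T_i$ is the normalized finite-difference velocity (carried
forward through momentary rests). The normal is transported with minimal
twist: with $U = T_i \times T_{i+1}$, if $\|U\|$ is below $10^{-10}$ the
normal is copied, otherwise it is rotated about $U/\|U\|$ by
$\theta = \arccos(T_i \cdot T_{i+1})$ (the dot product itself is a
cosine, so the arccosine is the only reading that produces a rotation
carrying $T_i$ to $T_{i+1}$). $B = T \times N$ closes a right-handed
orthonormal triad; an explicit re-orthogonalization after each step
prevents numerical drift. Antiparallel consecutive tangents — a
velocity reversal, which the transport rule leaves undefined — are
crossed by composing two quarter-turn rotations about an arbitrary
perpendicular axis, with a warning.

The initial normal $N_0$ is mathematically free. We take the direction
of the initial normal acceleration (Gram-Schmidt of $r''(t_1)$ against
$T_1$), because that choice rotates with the scene: any deterministic
rule built from fixed laboratory axes (e.g. "the coordinate axis least
aligned with $T_1$", available as `initial_normal()` and used as the
fallback for initially straight trajectories) breaks rotation
invariance of everything downstream by a constant twist about the
motion axis. With the equivariant choice, jointly rotating and
translating all meshes changes the final SH descriptors by $<10^{-11}$
in practice (bounded by $10^{-5}$ in the test suite).

Reorientation maps each vertex $v$ to $v^* = M (v - o)$, where the rows
of $M$ are $T, N, B$ at the mesh's time stamp and $o$ is the smoothed
trajectory point there: the direction of motion becomes the $+x$ axis.
The "standard basis" ablation used in cohort comparisons replaces this
with identity frames at the mesh mass centers, so the two analyses
differ in nothing but the reorientation.

## Spherical parameterization

SH expansion needs a bijection from the (volume-normalized, reoriented)
surface to the unit sphere. We use conformalized mean-curvature flow:
implicit Euler steps $x \leftarrow (M_t + \delta L_0)^{-1} M_t x$ with
the cotangent stiffness $L_0$ frozen at the input mesh and the lumped
mass matrix $M_t$ refreshed each step, with re-centering and rescaling
to unit mean radius after every step. Freezing $L_0$ is what prevents
the neck-pinch singularities of raw mean-curvature flow on protrusive
shapes. Numerical choices:

* step $\delta = (\text{mean edge length})^2$; much smaller steps leave
  elongated shapes far from spherical within the iteration cap, much
  larger ones destabilize strongly protrusive meshes.
* the true cotangent weights are kept, including negative ones (the
  cotangent stiffness is the P1 finite-element Laplacian and is positive
  semi-definite regardless); only numerically degenerate corners have
  their cotangents magnitude-capped, with a warning. Flooring all
  weights would distort the flow measurably.
* stopping: sphericity (radius sd/mean) below `tol = 0.02`, a stall
  (relative improvement $<10^{-4}$ for 25 iterations — the discrete
  flow has a resolution-dependent equilibrium whose residual sphericity
  on coarse elongated meshes is around 0.05), or `max_iters = 500`.
  Stalling above `tol` warns; above `fail_tol = 0.15` it is an error.

The flow limit is a *conformal* sphere map, and conformal maps of
elongated shapes concentrate area heavily. Left uncorrected this
systematically shrinks the low-degree content of the expansion: for a
2:1:1 ellipsoid the degree-1 coefficient ratio comes out near 1.2
rather than 2 (the exact conformal value for the spheroid is 1.20;
area-uniform would give 1.78). The defining property of the
eccentricity indices, however, is that an ellipsoid's expansion
terminates at degree 1 with coefficients equal to its semi-axes — the
same property that makes "all higher coefficients zero" characterize a
perfect sphere. We therefore finish with a **first-order parameter
normalization** (`sh_degree1_normalize()`, on by default): fit the
degree $\le 1$ expansion, giving a constant $c_0$ and a $3\times3$
degree-1 matrix $B$, move every sphere point to
$\mathrm{normalize}(B^{-1}(v - c_0))$, and iterate to a fixed point.
Any affinely mapped sphere (every ellipsoid) is exactly fixed under its
exact parameterization, so axis ratios are recovered essentially to
machine precision across ratios 0.5-3, while a sphere's identity map is
untouched. The step is rotation-equivariant, preserves mesh
connectivity, and in all tested shapes (including strongly protrusive
cells) leaves zero flipped spherical triangles. First-order
normalization of spherical parameterizations is standard practice in
SPHARM shape analysis; here it is what makes degree-1 ratios readable
as geometric eccentricities.

Angles follow the convention $\theta = \arccos(y)$, $\varphi =
\mathrm{atan2}(z, x)$ — the polar axis is $+y$, not $+z$. This pairing
makes the three degree-1 real harmonics proportional to the Cartesian
coordinate functions as $x \sim Y_{1,1}$, $y \sim Y_{1,0}$,
$z \sim Y_{1,-1}$, so `E_xy = |C_x(1,1)|/|C_y(1,0)|` is literally the
x-to-y elongation ratio with the motion axis first. (With a $+z$ pole
the same three ratios would pair wrong coefficients and be meaningless.)

## Spherical-harmonic descriptor and shape measures

Orthonormal real spherical harmonics, Condon-Shortley phase off, indexed
$j = l^2 + l + m + 1$, $k = (l_{\max}+1)^2$ basis functions;
$l_{\max} = 6$ by default (49 coefficients per coordinate, 147 per
shape). Coefficients solve the unweighted least-squares system over the
mesh vertices; vertex-area weights are available as an option. The
normalization convention cancels from all eccentricity ratios; absolute
values are used because degree-1 signs encode only pole alignment.

Derived measures: eccentricity indices `E_xy`, `E_xz` (and the redundant
`E_yz = E_xz / E_xy`, excluded from features); the L2 descriptor
distance; and the shape-change rate, the distance between consecutive
time points. The full 147-vector (including $l = 0$, which carries the
residual translation of the reorientation origin) enters distances; a
drop-degree-0 variant was considered and rejected to keep the literal
definition — the effect is negligible because reoriented meshes are
nearly centered.

## Features and statistics

Per cell, 26 features: median, raw median absolute deviation (no 1.4826
factor — plain "median absolute deviation"), and the 25th and 75th
percentiles (type-7 linear interpolation) of speed, curvature, torsion,
shape-change rate, `E_xy` and `E_xz`, plus the number of peaks of the
curvature and of the torsion series. Movement quantities are summarized
on the dense smoothed grid (that is the curve whose "graph" peaks are
counted; peaks are interior strict maxima after collapsing plateaus,
with an optional prominence threshold, default 0); shape quantities
exist only at observed mesh times. Cells with fewer than 6 usable time
points are excluded, as are meshes failing the closed-genus-0 check.

Downstream: column z-scoring (constants dropped with a warning),
tie-corrected Kendall correlations, a 2D embedding, stratified ten-fold
KNN cross-validation run on *identical fold partitions* for the
moving-frame and standard-basis tables (so the per-fold accuracy
differences are properly paired for the one-sample t-test), and
permutation importance (mean held-out accuracy drop over seeded column
shuffles). The embedding is a compact in-package implementation of the
uniform-manifold approach (fuzzy k-NN graph with smooth-knn bandwidth
calibration, probabilistic-union symmetrization, spectral
initialization, SGD with negative sampling; defaults
`n_neighbors = 20`, `min_dist = 0.1`, Euclidean metric), fully seeded.
All stochastic steps take explicit seeds recorded in their outputs.

## The synthetic generator

`generate_dataset()` emulates the reference simulation this kind of
pipeline is validated on: 250 unit-spaced time points, of which
$t = 1, 10, 20, \dots, 250$ (26 points) are observed; a near-spherical
unit-volume cell; a two-bump accelerate-decelerate-accelerate-decelerate
speed profile; one smooth, fully 3D direction change between $t=100$ and
$t=130$ (both azimuth and elevation turn, so curvature *and* torsion
peak there); and a pseudopod protruding along the motion direction with
length $0.6 \cdot \text{speed}/\text{max speed}$ cell radii over a 60°
cap, plus seeded low-degree SH surface noise of relative amplitude 0.02
standing in for rendered surface texture. Where the emulated conditions
fix a value (250 time points, the observation rule, the two-bump
pattern, unit volume) the defaults encode it; where they are only
qualitative (protrusion gain, cap width, noise amplitude, turn angle)
the defaults are one-time choices of plausible magnitude for an
actively migrating cell and are documented in `synthetic_cell_config()`.
Emitted meshes have their vertex mean exactly on the ground-truth path,
so trajectory recovery is testable to machine precision at zero noise.

What the generator does *not* emulate: real segmentation artifacts,
topology defects, resolution anisotropy, frame-to-frame correspondence
noise, or biological shape variety beyond a single directional
protrusion. Passing tests on it validate the geometry and statistics of
the pipeline, not segmentation robustness on microscope data.

`generate_cohort()` builds a two-group classification benchmark in which
both groups share the speed-profile family and differ only in pseudopod
amplitude, with one random 3D heading per cell. Movement features then
carry no group signal and laboratory-frame shape features are scrambled
by the random headings, so the benchmark isolates exactly the property
the moving frame is for.

## Problem sizes and runtimes

Defaults target interactive use on one CPU: subdivision-3 icospheres
(642 vertices) for single-shape analyses — the full ellipsoid
eccentricity computation runs in a few seconds — and subdivision-2
meshes (162 vertices) with a relaxed flow tolerance (`mcf_tol = 0.08`;
the degree-1 normalization makes coefficients insensitive to the exact
stopping point, which we verified to four decimals) for cohort-scale
work, where a 26-time-point cell fits in ~3 s and a 24-cell two-basis
cohort analysis completes in ~3 min. The test suite uses these sizes.

## Known limitations

* Genus-0, reasonably well-shaped meshes only; no repair or remeshing.
* The degree-1 normalization assumes an invertible degree-1 coefficient
  matrix; degenerate (nearly flat or point-symmetric) shapes fall back
  to the unnormalized map with a warning.
* GP hyperparameters $(\ell, v)$ are fixed, not learned; only
  $\sigma^2$ is optimized. Heavily irregular sampling would warrant
  learning $\ell$.
* Torsion from finite differences is noisy wherever curvature is small;
  interpret torsion features jointly with curvature.
* The frame is undefined for cells that never move; momentary rests are
  bridged by carrying the tangent forward.
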