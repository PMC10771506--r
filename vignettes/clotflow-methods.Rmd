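---
title: "clotflow: methods, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clotflow: methods, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clotflow` reconstructs the hemodynamic and transport environment of a
growing hemostatic plug from time-lapse intravital fluorescence imaging.
This vignette is the package's own account of the science inside it: the
models and their assumptions, every tunable parameter with its units and
default, the numerical choices, and what the tests do and do not demonstrate.

## 1. The imaging problem and the synthetic generator

Intravital microscopy of a laser-injured arteriole yields ~300 frames per
channel at 0.55 s/frame: a platelet channel (CD41) delineating the overall
clot, an activation channel (P-selectin) delineating the densely packed core,
and caged fluorescent albumin (cAlb) reporting plasma. Such animal datasets
are rarely shareable, so the package includes a first-class synthetic
generator whose defaults emulate their statistical structure:

* geometry: a nested pair of ellipses (core strictly inside the overall
  region) following an analytic growth schedule — linear or saturating axis
  growth, optional plateau, optional embolization modelled as an
  instantaneous area drop by a prescribed fraction followed by regrowth;
* intensities (8-bit): foreground ~ Normal(180, 30) clipped to [0, 255],
  background ~ Normal(30, 10), plus isolated salt-noise pixels at 255 with
  density 0.02 outside the clot. The essential feature is that *noise pixels
  are as bright as clot pixels*, differing only in spatial sparsity — this is
  what makes plain intensity denoising ineffective and motivates the
  binarize-then-median-filter design;
* acquisition: 0.55 s/frame; pixel size defaults to 0.5 µm/px (the source
  imagery does not fix a value; it is configurable and all downstream
  quantities are in µm);
* vessel: an axis-aligned lumen 30–100 µm in diameter with a circular-arc
  indentation of one wall at the injury site; the cAlb channel adds a
  stagnation pool in the indentation for qualitative use only.

What the generator does **not** emulate: point-spread blur, photobleaching,
depth-dependent attenuation, non-elliptical lobed clot shapes, or multiple
interacting clots. Tests passing on synthetic data therefore demonstrate the
correctness of the algorithms under controlled statistics, not performance
on arbitrary real microscopy.

## 2. Segmentation chain

Per frame: binarization → median filter → Gaussian filter → k-means (k = 2)
→ Canny edges → largest-perimeter edge-graph component → ordered closed loop.

Parameters (`segmentation_params()`):

| parameter | default | units | role |
|---|---|---|---|
| `binarize` | Otsu | — | threshold from the intensity distribution; a percentile rule (q %) is exposed for the sensitivity sweep |
| `median_kernel` | 3 | px (odd) | removes sparse bright noise from the binary image |
| `gaussian_sigma` | 1 | px | closes interior holes; output re-binarized at 0.5 |
| `canny_low`, `canny_high` | 0.1, 0.3 | fraction of max gradient | hysteresis thresholds |
| `connectivity` | 8 | — | adjacency of the edge-pixel graph |
| `seed` | 1 | — | k-means restarts (10) |

Design notes:

* Otsu was chosen as the default threshold rule because the binarization is
  specified only as distribution-based; the percentile rule spans the
  operating window in the sensitivity study.
* k-means runs on the *denoised grayscale* image (the Gaussian-smoothed
  binarized frame), with the higher-mean cluster taken as clot. After
  pre-processing the histogram is essentially bimodal, which is why two
  clusters suffice.
* Canny gradients are computed with zero padding, so a clot touching the
  frame edge still closes its edge ring.
* Canny rings on binary masks are locally 1–2 px thick, which dead-ends
  nearest-neighbour boundary walks. The loop is therefore ordered by polar
  angle about the component centroid, taking per angular bin the pixel whose
  radius is closest to the bin mean (centered in the ring). This yields the
  single outer envelope loop — interior pore edges are intentionally
  dropped, and the enclosed pore space remains part of the clot domain.
* Component tie-breaks on equal perimeter: larger enclosed area, then lowest
  centroid row.
* Frames where any stage fails are flagged and bridged by temporal
  interpolation between neighbouring good frames; more than 20 % failures
  aborts the stack.

Measured on synthetic ellipses (semi-axes 10–40 µm, arbitrary rotation,
default noise), the relative area error of the chain is well under 10 %
(typically < 1 %); the acceptance script recomputes this bound.

## 3. Boundary geometry and temporal interpolation

The ordered boundary pixels become the control points of a closed *uniform*
B-spline (degree 3 by default; degrees 1–2 available). Using pixels as
control points smooths the stair-step raster artifact while staying within a
fraction of a pixel of the loop (the cubic deviation from a control polygon
with unit steps is ≤ 1/6 of the local second difference).

Frame-to-frame correspondence uses equal-angle ray tracing: `n_rays = 180`
rays from the region's center of mass, each intersected exactly with a dense
polygonal sampling of the spline; for non-star-shaped curves the
intersection nearest the center is taken, guaranteeing one matched point per
ray. Intermediate boundaries are linear interpolations of matched points and
centroids. `n_sub = 11` sub-steps per 0.55 s frame gives the 0.05 s flow
time step; a smaller solver step than the imaging interval is required for a
stable coupled solution, and 0.05 s resolves the advective time scale
h/U ≈ 2 ms × 25 at the default mesh.

Kinematics: area by the shoelace formula on the matched polygon; aspect
ratio as sqrt(λmax/λmin) of the second central area-moment tensor — a
rotation-invariant definition that equals a/b on an ellipse (the source
plots do not define their metric; this one is testable). Rates use central
differences after a 5-frame moving average, filtering frame-rate
segmentation jitter.

The down-sampling fidelity check removes two of every three frames,
re-interpolates, and reports the mean matched-point distance to the original
boundaries; on smooth growth this is ~0.15 µm, an order below the 1 µm
scale of interest.

## 4. Fictitious-domain marking and material fields

The vessel mesh is fixed for the whole run; all clot motion lives in nodal
indicator fields (point-set front tracking). Per region and sub-step one
Laplace problem is solved: I = 1 on every node of an element containing a
boundary-curve point, I = 0 on the outer domain boundary, membership where
I ≥ 1 − ε with ε = 10⁻² (the threshold only needs to separate the interior
plateau I ≈ 1 from the exterior decay; any small value works). This is a
single symmetric sparse solve per region — negligible next to a flow step.

Two practical choices:

* The marking rule sets I = 1 on *all* nodes of boundary-containing
  elements, so the marked set extends up to one element layer outward; at
  mesh size h the marked area of a disk of radius r is ≈ π(r+h)². The
  tests assert exactly this one-layer bound (and agreement with an even–odd
  point-in-polygon oracle away from that layer) rather than pretending
  sub-element accuracy.
* Where the clot reaches past the vessel wall, its out-of-domain boundary
  points are clamped onto the wall (within 2h) so the I = 1 ring closes one
  element layer inside; the wall nodes themselves keep the Dirichlet zero,
  which wins any conflict.

Material fields (µm units): porosity φ = φ_core inside the core, φ_shell in
the shell (overall minus core, with core membership intersected into the
overall), 1 outside; hindered diffusivity likewise (D_core ≤ D_shell ≤
D_free enforced). Presets carry the two case-study parameter sets:
wild-type φ core/shell 0.2/0.3 with D = 0.4/0.8 µm²/s, and the
contraction-impaired knockout 0.2/0.4 with 0.5/1.0 µm²/s; free plasma
D = 60 µm²/s. Permeability uses the Kozeny–Carman law
K = φ³/(150(1−φ)²), which as printed is dimensionless; the Brinkman term
needs an area, so K is multiplied by L_ref² with L_ref = 3 µm — a platelet
diameter, the natural grain scale of a platelet aggregate. L_ref is
config-exposed because this dimensionalisation is a modelling choice, not a
measured quantity.

## 5. Flow and transport solvers

Flow: ρ(∂u/∂t + u·∇u) = −∇p + µ∇²u − (µ/K)u inside the clot, ∇·u = 0,
with ρ = 1.06 g/cc, µ = 4.0 cP, a parabolic inlet with 1300 µm/s peak
(steady by default — the measured quantity is a single centerline velocity;
a sinusoidal modulation flag exists but is off), no-slip walls, do-nothing
outlet. Discretisation: equal-order P1–P1 with SUPG/PSPG; the stabilisation
parameter is the classical inverse-estimate form

τ = [ (2ρ/Δt)² + (2ρ|a|/h)² + (4µ/h²)² + σ² ]^{-1/2},  σ = µ/K·χ_clot,

which has the convenient Darcy limit τ → K/µ inside a low-permeability
clot, turning the PSPG term into the standard stabilised-Darcy pressure
form. Time stepping is backward Euler; convection is Picard-linearised
(tolerance 10⁻⁶, max 25 iterations — at Re ~ 10⁻² two to three suffice).
Internal units are SI; inputs/outputs are µm-based.

Verified limits: plane Poiseuille recovered to < 2 % (centerline and
profile RMS) at h = d/20 with error decreasing under refinement; a uniform
φ = 0.2 slab spanning the channel reproduces the 1D Darcy–Brinkman axial
pressure gradient to < 4 %; zero inflow yields machine-zero velocity.

Transport: φ ∂c/∂t + u·∇c = ∇·(φD∇c) in non-conservative advective form
with porosity-weighted storage and diffusion (with discretely
divergence-free u the conservative and advective forms agree in the
continuum; the φ-weighted storage makes the clot's pore volume, not its
bulk, hold solute). SUPG streamline stabilisation plus a
continuous-interior-penalty term γ Σ_F h_F² |u_F| ∫_F [∂n c][∂n v]
(γ = 0.01) control advective oscillations; the storage matrix is lumped.
Inlet c = 0, advective outflow, no-flux walls; a `closed` mode removes all
Dirichlet data for conservation checks, where the porosity-weighted mass is
conserved to machine precision.

Sharp uncaging fronts at the clot interface are genuinely under-resolved at
the default mesh when the free-stream cell Péclet is O(10²): the scheme then
overshoots [0, 1] locally by 10–30 % and emits a warning carrying the cell
Péclet number. The overshoot bound |c − [0,1]| ≤ 0.05 holds in resolved
regimes. We chose not to add nonlinear shock-capturing diffusion: its
artificial diffusivity (~h|u|/2) would exceed the physical hindered
diffusivity inside the clot by an order of magnitude and corrupt the decay
curves that are the scientific output. Volume-averaged decay quantities are
insensitive to the localized overshoot (they remain monotone, with the core
decaying slower than the shell, as the tests assert).

## 6. Quantification

* Traction: F = ∮(−pI + µ(∇u+∇uᵀ))·n ds on the spline boundary, outward
  normal, with P1 element gradients at quadrature points (consistent with a
  non-body-fitted solve); pressure and viscous parts reported separately,
  per unit out-of-plane depth in nN/µm. The closed-curve pressure integral
  of a constant field vanishes to quadrature precision, and the integral
  Richardson-converges under quadrature refinement.
* Reynolds number: Re = ρ(U_peak/2)d/µ. The factor ½ is the parabolic
  mean-to-peak ratio of a cylindrical tube, retained as the vessel-flow
  convention (a 2D plane channel would give ⅔; both land in the creeping
  regime 10⁻³–10⁻², e.g. 8.6×10⁻³ at d = 50 µm).
* Decay curves: porosity-weighted lumped-area averages over region member
  nodes, normalized to the pulse value.
* Phase portrait and embolization: (total loading, area) pairs per
  checkpoint. Embolization = the first run of ≥ 3 checkpoints with negative
  smoothed area rate starting no earlier than the running force maximum
  minus the smoothing half-width; within the run, the index is placed at
  the steepest single-step area drop, which hits a step-drop schedule
  exactly and has produced zero false positives over random monotone-growth
  schedules. Both the vector-sum magnitude and the sum of magnitudes are
  emitted (plots use the vector sum).
* Sensitivity: Latin-hypercube sampling over percentile threshold (70–90),
  median kernel (3–7 px), Gaussian σ (0.5–2 px) and Canny thresholds
  (0.05–0.15 / 0.2–0.4), n = 30; reported as the time-averaged coefficient
  of variation of area and aspect ratio across samples. These windows span
  the operating range within which the chain should be — and measures as —
  robust (area CV ≈ 3 %, aspect CV ≈ 1.5 % on the default stack).

## 7. Problem sizes and degenerate inputs

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes that exercise every mechanism: 128–176 px frames, 2–30
frames per stack, meshes of ~500–900 nodes (h = d/10 … d/20), coupled runs
of a few seconds of physical time. All scale linearly upward via
configuration.

Degenerate inputs are handled explicitly: constant-intensity frames warn
and return background; all-identical pixels abort clustering; empty label
masks and edge-free masks raise per-frame segmentation failures (bridged by
interpolation); boundaries finer than the mesh raise a refinement error;
φ = 1 must bypass the Brinkman term rather than evaluate Kozeny–Carman;
zero-area boundaries abort the kinematics.

## 8. Known limitations

* 2D only; forces are per unit depth and not directly comparable to 3D
  magnitudes.
* One clot per field of view; no fragment tracking after embolization.
* The Brinkman drag uses element-mean nodal coefficients, smearing the clot
  interface over one element.
* Steady inflow; pulsatility is available only as a simple modulation.
* The marked clot domain is biased outward by up to one element layer
  (Section 4); quantities derived from membership inherit an O(h/r) bias.
* Segmentation assumes the clot is the largest bright coherent structure;
  dim or fragmented clots will defeat the largest-perimeter rule.
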