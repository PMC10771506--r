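# clotflow

Quantifying the flow environment of a growing hemostatic plug (clot) from
intravital microscopy. Real-time fluorescence imaging of laser-injured mouse
arterioles shows *where* the clot is, frame by frame, but not the blood flow,
pressure loading, or solute transport around and through it — none of which
are directly measurable in vivo. `clotflow` closes that gap: it converts a
time-lapse image stack of a growing, deforming clot into a moving
computational domain on a fixed vessel mesh, solves for the viscous flow and
solute transport in and around the heterogeneous porous clot, and reports the
derived mechanics — clot kinematics, flow-induced traction loading, and
intra-clot solute decay.

It is aimed at researchers in thrombosis/hemostasis biomechanics who have
multi-channel intravital stacks (platelet marker for the overall clot, an
activation marker for the dense core, caged albumin for plasma) and want
simulation-grade quantities out of them. Since such datasets are rarely
shareable, the package also ships a synthetic-imaging generator that emulates
their statistical structure with exact ground truth, so the entire pipeline
is testable end to end.

## The model

**Segmentation.** Each frame is binarized from its intensity distribution
(Otsu by default), denoised with a median filter (removing sparse bright
noise pixels whose intensity matches the clot) and a Gaussian pass (closing
interior holes), clustered by k-means with k = 2, and edge-detected with a
Canny filter. Edge pixels form a graph under 4/8-adjacency; the connected
component with the largest perimeter is the clot boundary.

**Geometry.** The ordered boundary pixels become control points of a closed
cubic B-spline. Boundaries at different frames are matched by equal-angle ray
tracing from each frame's center of mass, and intermediate boundaries at
simulation sub-steps are obtained by linear interpolation of the matched
points (0.55 s frame interval, 11 sub-steps by default).

**Fictitious-domain marking.** On a fixed triangulated vessel mesh, clot
membership at each sub-step comes from a Laplace indicator solve
(`∇²I = 0`, I = 1 on nodes of elements containing boundary points, I = 0 on
the outer boundary, members where `I ≥ 1 − ε`). Porosity and hindered
diffusivity are assigned per region (core / shell / free plasma), and
permeability follows the Kozeny–Carman law

    K = φ³ / (150 (1 − φ)²)

dimensionalised by a platelet-scale reference length (default 3 µm).

**Flow and transport.** Brinkman–Navier–Stokes flow

    ρ(∂u/∂t + u·∇u) = −∇p + µ∇²u − (µ/K) u·χ_clot ,   ∇·u = 0

with a parabolic inlet (peak 1300 µm/s, ρ = 1.06 g/cc, µ = 4.0 cP), no-slip
walls and a traction-free outlet, discretised with equal-order P1–P1
elements stabilised by SUPG/PSPG (backward Euler, Picard linearisation).
Solute transport `φ ∂c/∂t + u·∇c = ∇·(φD∇c)` uses SUPG plus
continuous-interior-penalty gradient-jump stabilisation; caged-albumin
uncaging pulses set c = 1 over the clot.

**Quantification.** Boundary traction `F = ∮ σ·n ds` with
`σ = −pI + µ(∇u + ∇uᵀ)` split into pressure and shear parts (nN per µm
depth); volume-averaged solute decay per region; Reynolds number; a
force–area phase portrait with an embolization detector (sustained negative
smoothed area rate after the running force maximum); and a Latin-hypercube
sensitivity sweep of the segmentation parameters.

## Worked example

```r
library(clotflow)

# 1. a synthetic 12-frame stack of a growing elliptical clot with core
scene <- synthetic_scene(
  image_shape = c(128, 128),
  schedule = make_growth_schedule(12, base_axes = c(8, 6),
                                  growth_rate = c(0.3, 0.2),
                                  center = c(32, 30), saturation_tau = 6),
  core_scale = 0.5, pixel_size = 0.5, frame_interval = 0.55, seed = 1)
imgs <- render_stack(scene)

# 2. segment every frame and fit closed B-spline boundaries
seg <- function(st) {
  b <- segment_stack(st, segmentation_params())
  lapply(seq_along(b), function(f)
    fit_spline_boundary(b[[f]], degree = 3, pixel_size = 0.5,
                        time = (f - 1) * 0.55))
}
domain <- dynamic_clot_domain(seg(imgs$channels$CD41),
                              seg(imgs$channels$PSelectin),
                              frame_interval = 0.55, n_sub = 4)
head(compute_kinematics(domain), 3)
#>   time   area aspect dA_dt dAR_dt
#> 1 0.00 148.20   1.32  7.36   0.00
#> 2 0.55 159.81   1.35  7.36   0.01
#> 3 1.10 172.14   1.33 10.64   0.01

# 3. coupled flow + transport on a fixed vessel mesh with an injury pocket
mesh <- build_vessel_mesh(length = 64, diameter = 50,
                          injury = list(center_x = 32, depth = 4, width = 16),
                          h = 2.5)
sim <- run_coupled_simulation(domain, mesh, wt_params(), t_end = 2.2)

# 4. traction loading on the clot boundary (nN per um depth)
loading_series(sim$checkpoints, mesh)[c(1, 3, 5),
    c("time", "pressure_mag", "shear_mag", "total_mag")]
#>   time pressure_mag shear_mag total_mag
#> 1  0.0       0.0867  2.58e-05    0.0867
#> 3  1.1       0.0905  4.21e-05    0.0905
#> 5  2.2       0.1030  3.30e-05    0.1030

# 5. caged-albumin decay by region
#>   time  clot  core shell
#> 1 0.00 1.000 1.000 1.000
#> 2 0.55 0.419 0.965 0.187
#> 5 2.20 0.302 0.836 0.102

reynolds_number(flow_config(), 50)
#> [1] 0.0086125
```

The kinematics track the prescribed growth (area rising from 148 µm², rates
positive throughout). The loading is overwhelmingly pressure-driven — shear
is three orders of magnitude smaller — and grows with occlusion. The
caged-albumin average collapses quickly in the loose shell (0.10 after
2.2 s) while the dense core retains 0.84 of its pulse: transport in the core
is effectively arrested. The Reynolds number 8.6×10⁻³ confirms creeping flow.

The same chain is available as an orchestrated pipeline with on-disk
artifacts and a JSON manifest (`run_pipeline()`, stages `synth`, `segment`,
`track`, `simulate`, `quantify`, `sensitivity`), and as a thin CLI at
`inst/cli/clotflow.R`.

## Vignette

`vignettes/clotflow-methods.Rmd` documents the model assumptions, parameter
choices and units, the numerics (stabilisation, tolerances, degenerate
inputs), what the synthetic generator does and does not emulate, and known
limitations.
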