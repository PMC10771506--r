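Package: clotflow
Title: Dynamic Clot Reconstruction and Porous-Media Hemodynamics from
    Intravital Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline that converts time series of intravital
    fluorescence microscopy images of a growing and deforming hemostatic plug
    (clot) into a dynamic computational domain, and simulates viscous blood
    flow and solute transport around and through the heterogeneous porous clot
    on a fixed background mesh. Stages: synthetic image generation with ground
    truth, automated per-frame boundary segmentation (binarization, median and
    Gaussian denoising, k-means clustering, Canny edges, largest-perimeter
    component), closed B-spline boundary parameterisation with equal-angle
    temporal interpolation, Laplace-indicator marking of clot nodes on a fixed
    vessel mesh, Kozeny-Carman permeability and region-wise porosity and
    hindered-diffusivity fields, a SUPG/PSPG stabilised finite-element
    Brinkman-Navier-Stokes flow solver coupled to stabilised
    advection-diffusion solute transport, and quantification of clot
    kinematics, boundary traction loading, caged-albumin decay, and
    embolization events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    EBImage,
    lhs,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
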