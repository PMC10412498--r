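Package: cardioriis
Title: Image-Based Systolic Left-Heart Hemodynamics with Resistive Immersed Valves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study systolic blood flow in the left ventricle, left atrium
    and aortic root under healthy and mitral-regurgitant conditions. Provides a
    synthetic cine-MRI-like phantom of the left heart (analytic geometry, prescribed
    systolic wall motion, rendered short/long-axis image stacks, and radial-plane
    mitral leaflet traces), a short/long-axis merging (SLAM) image fusion step,
    mitral valve surface reconstruction from ring-wise B-spline fitting, harmonic
    mesh-motion extension, an arbitrary Lagrangian-Eulerian incompressible
    Navier-Stokes solver with SUPG/PSPG stabilization, resistive immersed implicit
    surface (RIIS) valve penalties and a sigma-model large-eddy subgrid viscosity,
    and postprocessing of clinical hemodynamic indices (stroke volume, cardiac
    output, regurgitant volume and fraction, transvalvular velocities, turbulence
    ratio and wall shear stress).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    splines,
    yaml,
    jsonlite,
    RNifti,
    tools
LinkingTo: Rcpp, RcppArmadillo, RcppEigen
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
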