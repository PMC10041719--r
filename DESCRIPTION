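Package: stenoflow
Title: Pulsatile Hemodynamics in Idealized Coronary Stenoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved simulation of pulsatile, shear-thinning blood flow
    through parametric axisymmetric stenosed vessels under pressure boundary
    conditions derived from fractional flow reserve (FFR) measurements.
    Provides a Chorin-style projection solver for the incompressible
    Navier-Stokes equations on body-fitted structured grids, Carreau
    rheology, synthetic cardiac-cycle pressure waveforms, wall shear stress
    post-processing (TAWSS, OSI, RRT), probe-point pressure and velocity
    time series, grid-refinement convergence studies, and a configurable
    severity sweep from 30% to 80% diameter stenosis with CSV, legacy-VTK
    and Markdown report outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
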