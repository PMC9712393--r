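Package: surbop
Title: Band-Selective Universal-Rotation Pulse Design by Quaternion GRAPE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Optimal-control design of band-selective universal-rotation
    (UR) radio-frequency pulses for high-field NMR, using a quaternion
    formulation of spin-1/2 propagation and a GRAPE-type projected
    gradient descent with analytic adjoint (costate) gradients.  The
    flagship application is 90 and 180 degree pulses that cover the full
    aliphatic 13C chemical-shift band at 1.2 GHz spectrometers within a
    15 kHz rf-amplitude budget while leaving the aromatic and carbonyl
    bands untouched.  Includes a shaped-pulse response simulator over
    offset/B1 grids, passband ripple and stopband leakage metrics,
    Gaussian pulse-cascade comparison shapes (Q3, Q5, G4), and readers
    and writers for Bruker-style JCAMP-DX shape files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
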