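Package: tevgsim
Title: Pulsatile Hemodynamics and Protein Adsorption on Tissue-Engineered Vascular Grafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of albumin and fibrinogen adsorption on the
    luminal surface of a small-diameter tissue-engineered vascular graft (TEVG)
    under pulsatile flow. Couples a Fourier-harmonic representation of periodic
    pressure waveforms, analytic per-harmonic Womersley solutions of pulsatile
    laminar flow in a cylindrical lumen (with Reynolds number, Hagen-Poiseuille
    pressure drop and wall shear stress diagnostics), a reduced-order thick-wall
    Lame elastic model of the graft wall, Langmuir-type reversible/irreversible
    protein-surface adsorption kinetics (well-mixed reactor form), and an
    axisymmetric finite-volume advection-diffusion transport model with a
    reactive wall boundary. Ships packaged scenarios contrasting constant and
    space-time dependent outlet velocity conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
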