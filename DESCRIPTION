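Package: acoustochip
Title: Acoustofluidic Spheroid-on-Chip Multiphysics Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled two-dimensional finite-element simulation of an
    acoustically actuated perfusion microwell for tumor-spheroid culture.
    Solves first-order thermoviscous acoustics in the frequency domain,
    the time-averaged acoustic-streaming mean flow combined with perfusion,
    and steady oxygen/glucose reaction-diffusion with Michaelis-Menten
    consumption and a solubility-jump interface at the spheroid surface.
    Classifies necrotic, quiescent and proliferating zones of the spheroid,
    computes wall shear stress and lift on the aggregate, and reproduces
    actuation-amplitude and flow-rate parameter sweeps, including a
    Rayleigh-streaming validation benchmark in a rectangular cavity.
    Includes its own block-structured triangular mesh generator with
    viscous-boundary-layer grading and a vectorised P1/P2 assembly core
    built on sparse matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
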