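Package: wmrve
Title: Multiscale Homogenization of Brain White Matter with Embedded Axon Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Histology-informed micromechanical modelling of brain white matter.
    Generates random axon-fiber networks inside a cubic representative volume
    element from fitted distributions of fiber diameter (generalized extreme
    value), straightness (beta) and orientation (bivariate von Mises), evaluates
    one-term Ogden constitutive laws for the ground matrix and embedded fibers
    with a recruitment-stretch mechanism for tortuosity, homogenizes the seven
    canonical loading modes with either affine micro-kinematics or a periodic
    finite-element engine with embedded truss fibers, and identifies the
    matrix and fiber material parameters from stress-stretch curves by a
    two-step bounded least-squares procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
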