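Package: lrpop
Title: Locally Regulated Spatial Population Models, Genealogies and
    Scaling Limits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of spatial birth-death point processes with
    kernel-smoothed density dependence (birth, establishment and death rates
    all respond to local density measured by convolution), the lookdown
    representation of the same dynamics with levels, lines of descent and
    Newick genealogy export, finite-difference solvers for the nonlocal and
    classical reaction-diffusion scaling limits including the porous medium
    equation with logistic growth, backward-in-time ancestral lineage
    diffusions in travelling waves with closed-form speed measures, and the
    linear-stability (clumping) dispersion relation for spatially constant
    equilibria.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
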