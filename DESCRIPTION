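Package: baseflip
Title: Free-Energy Analysis of DNA Base Flipping by Adaptive Biasing and
    the String Method
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for computing base-flipping free-energy landscapes of
    DNA and minimum free-energy paths of protein-DNA binding at desk scale.
    Provides pseudodihedral and Cartesian collective variables with analytic
    gradients, a seeded BAOAB Langevin dynamics engine with pluggable bias
    and restraint forces, a capped adaptive biasing potential over one or
    two collective variables, graded backbone-restraint paradigms, the
    string method in collective variables with restrained mean-force
    estimation and per-image confidence intervals, free-energy surface
    construction and analysis, and Kabsch/iterative structural superposition
    with pooled shared-atom RMSD for flipped-base meta-analysis. Includes a
    synthetic-system module: analytic benchmark potentials (double well,
    Muller-Brown, separable periodic) and a coarse-grained bead-spring DNA
    duplex with breakable base-pair bonds whose central cytosine can flip
    between intrahelical and extrahelical states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    ggplot2,
    rlang,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
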