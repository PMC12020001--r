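Package: rosewater
Title: Phase Diagrams of a 2D Hydrogen-Bonding Water Model by Unsupervised Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements a two-dimensional water model of Lennard-Jones discs
    with an explicit, orientation-dependent hydrogen-bonding pair potential
    (a 3-petal rose angular term under a double-sided cubic distance switch),
    together with the machinery needed to map its pressure-temperature phase
    diagram: an NPT molecular-dynamics engine (velocity Verlet, velocity
    rescale and stochastic velocity rescaling thermostats, Berendsen and
    stochastic cell rescale barostats), constant-pressure nested sampling
    with partition-function thermodynamics, structural and thermodynamic
    observables (angular distribution functions, bond-orientational order,
    hydrogen-bond statistics, diffusion, fluctuation response functions),
    and an unsupervised machine-learning pipeline (MDS, Isomap, spectral
    embedding, t-SNE; k-means, Ward, DBSCAN; sequential diffusion peeling)
    that turns simulation observables into phase-label grids and scores them
    against reference diagrams.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    vegan
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
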