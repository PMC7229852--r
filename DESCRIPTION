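Package: origamiAccess
Title: Mechanics and Enzyme Accessibility of Coarse-Grained DNA Origami Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of coarse-grained (oxDNA) molecular dynamics trajectories of
    DNA origami nanostructures. Provides readers and writers for oxDNA topology and
    configuration files, cadnano design annotation and PDB particle extraction; a
    global-mechanics pipeline (Kabsch alignment, per-nucleotide RMSF, positional
    covariance eigenmodes, mode collinearity, trajectory projections, free-energy
    profiles by Boltzmann inversion, two-state statistics and substructure
    synchronization); a recognition-site catalog with crossover flagging; and a
    rigid-body docking method that scores the steric accessibility of restriction
    endonuclease recognition sites per strand side via maximum/minimum distance maps.
    Deterministic synthetic-scene generators (jittered duplexes, multi-helix rafts
    with scheduled gaps, planted double-well trajectories, probe clouds) support
    fully self-contained validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    bio3d
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'pdb-io.R'
    'rigid.R'
    'helix.R'
    'accessibility.R'
    'cadnano.R'
    'fes.R'
    'oxdna-io.R'
    'fixtures.R'
    'modes.R'
    'origamiAccess-package.R'
    'sites.R'
    'pipeline.R'
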