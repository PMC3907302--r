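Package: beamfilm
Title: Beam-Film Simulation and Analysis of Meiotic Crossover Patterning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation of meiotic crossover (CO) patterning by
    the beam-film stress-relief mechanism, together with the descriptor
    toolkit used to characterise CO patterns: coefficient of coincidence
    (CoC) curves and the interference distance L_CoC, event distributions,
    inter-CO distances with maximum-likelihood gamma-shape fitting, CO
    position histograms, crossover homeostasis and obligatory-CO (zero-CO)
    parameter sweeps, non-interfering CO scenarios, and grid-search fitting
    of simulation parameters to experimental per-bivalent CO-position data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), MASS, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'accessors.R'
    'params.R'
    'precursors.R'
    'patterning.R'
    'descriptors.R'
    'experiments.R'
    'io.R'
    'cli.R'
    'utils.R'
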