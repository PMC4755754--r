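Package: tjclamp
Title: Single-Channel Analysis of Trans-Tight-Junction Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-channel currents recorded across
    epithelial tight junctions. Provides a continuous-time Markov gating
    simulator for paracellular claudin-2 channels and a recording emulator
    (seal leak, Gaussian noise, Bessel filtering, voltage protocols); trace
    idealization by half-amplitude threshold crossing with event
    classification and NPo statistics; all-points amplitude histograms with
    Gaussian-mixture fits; log-binned dwell-time histograms and
    maximum-likelihood exponential mixture fits with kinetic state-count
    selection; voltage-ramp baseline subtraction, current-voltage fitting and
    reversal potentials; Goldman-Hodgkin-Katz dilution and biionic
    permeability ratios, Kimizuka-Koketsu absolute sodium permeability, and
    epithelial equivalent-circuit algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'tjclamp-package.R'
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'gating.R'
    'protocols.R'
    'filtering.R'
    'render.R'
    'scenarios.R'
    'idealize.R'
    'kinetics.R'
    'ramps.R'
    'ionic.R'
    'permeability.R'
    'circuit.R'
    'stats-helpers.R'
    'io.R'
    'pipeline.R'
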