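Package: stackdyn
Title: Monomer Exchange Dynamics in Hydrogen-Bonded Supramolecular Polymer Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis and rare-event kinetics for supramolecular
    polymers built from quadruple-hydrogen-bonded (ureido-pyrimidinone-type)
    dimers that stack into one-dimensional fibres. Provides switching-function
    hydrogen-bond coordination counting, per-monomer radial distribution
    functions, Shrake-Rupley solvent-accessible surface area, aggregation
    propensity and inter-stack contacts, dimer planarity, SOAP power-spectrum
    descriptors with the frame-to-frame tauSOAP and LENS dynamic descriptors,
    Gaussian-mixture classification of monomer dynamic domains with
    defect/self-healing event detection, and infrequent-metadynamics
    timescale estimation (bias-exponential time rescaling, Poisson CDF
    fitting, free-energy-surface reweighting). A kinetic Monte Carlo
    generator produces synthetic stack trajectories with planted exchange
    dynamics and bias traces with known rates so the whole pipeline is
    testable without molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
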