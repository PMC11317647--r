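Package: poreperm
Title: Ion Permeation and Pore Analysis for Channel Molecular Dynamics
    Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn molecular dynamics trajectories of ion channels
    into quantitative permeation observables: directional permeation event
    detection through a pore cylinder, single-channel conductance and
    permeability ratios, HOLE-style maximal-inscribed-sphere pore radius
    profiles, selectivity-filter geometry time series, ion hydration and
    coordination analysis, nearest-ion (knock-on) proximity statistics,
    time-averaged 3D density maps in OpenDX format, and reconstruction of
    umbrella-sampling potentials of mean force with a self-consistent WHAM
    solver and bootstrap errors. A synthetic-trajectory generator with
    analytically known ground truth (drift-diffusion crossers, hydration
    shells, biased samples from analytic free-energy surfaces, toy pores)
    makes every stage verifiable without large simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'poreperm-package.R'
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'selection.R'
    'trajectory-io.R'
    'synthetic.R'
    'permeation.R'
    'pore-geometry.R'
    'solvation.R'
    'density.R'
    'pmf.R'
    'cli.R'
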