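Package: xecest
Title: HyperCEST Z-Spectrum Analysis and Xenon Contact Statistics for
    Cage-Tagged Membrane Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of hyperpolarized 129Xe hyperCEST z-spectra of
    cryptophane-tagged membrane proteins and of molecular-dynamics
    trajectories of the tagged systems. Implements the exponential-Lorentzian
    multi-resonance z-spectrum model with the mechanistic mapping from xenon
    exchange and relaxation rates to resonance amplitude and width,
    weighted nonlinear least-squares fitting with BIC model selection,
    per-scan spectrum integration into z-spectra, xenon contact-probability
    analysis of trajectories (per-residue counts, per-frame environment
    categories, site-cluster probabilities), internal Calpha-H order
    parameters after rigid-body alignment, and seeded synthetic-data
    generators with analytic ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
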