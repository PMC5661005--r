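Package: columnet
Title: Two-Layer Cortical Column Networks for Sensorimotor Object Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator for networks of laterally connected cortical columns
    that learn and recognize objects from sequences of (location, feature)
    sensations. Each column pairs a minicolumn-structured input layer, which
    combines a sensory feature with an allocentric location signal into a
    sparse context-specific code, with an object-pooling output layer whose
    lateral connections let neighboring columns vote on object identity.
    Neurons follow the Hierarchical Temporal Memory model: binary synapses
    gated by scalar permanences, dendritic segments acting as independent
    pattern detectors, and Hebbian-style segment learning. Includes a
    synthetic object world, ideal-observer baselines with and without
    location information, and seeded experiments measuring convergence
    speed, object capacity, and robustness to sensory and location noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
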