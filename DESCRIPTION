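Package: cytodeliver
Title: Krogh-Cylinder Modelling of In Vivo Cytosolic Protein Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation of receptor-targeted cytosolic protein and
    peptide delivery to solid tissue. A capillary supplying a concentric annulus
    of tissue (Krogh cylinder) is discretised radially; six coupled species --
    free interstitial agent, free surface receptor, surface complex, cytosolic
    agent, free cytosolic target and the inhibitory complex -- evolve under
    extravasation, interstitial diffusion and convection, receptor binding and
    internalization, endosomal escape, and blocking or catalytic target
    inactivation. Includes plasma dosing regimens (repeated and cold dosing),
    outcome metrics (maximum inhibition, time-integrated inhibitory effect,
    delivery timing, penetration depth), affinity sweeps and optimal-affinity
    search, and bundled tissue/agent presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
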