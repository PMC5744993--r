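Package: pappnet
Title: Mechanistic Resistance-Network Model of Passive Cell-Monolayer Permeability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts passive apparent permeability (P_app) of Caco-2 and MDCK
    cell monolayers at pH 7.4 from physicochemical descriptors using a
    resistance-network model with three parallel permeation pathways
    (paracellular, cytosolic/transcellular, lateral), each composed of serial
    resistances: unstirred water layers, tight-junction pores with Renkin
    sieving and an electric-field speciation weighting, cytosol, filter
    support, hexadecane-slab membrane barriers with a microvilli surface
    factor, and an along-membrane lateral route. Includes an intrinsic
    black-lipid-membrane permeability submodel, route-dominance
    classification, dataset curation and evaluation utilities, and a seeded
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
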