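Package: pcmorph
Title: Purkinje Cell Morphometry, Spine Taxonomy and Spatial Demographics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative Purkinje cell morphometrics from SWC-style
    dendritic reconstructions: branch decomposition, Sholl profiles, arbor
    extent and caliber statistics; dendritic spine classification (thin,
    mushroom, branched, cluster), densities and spine-to-surround volume
    fractions; rule-based primary-dendrite morphology, orientation and foliar
    classifiers with species-specific thresholds; and one-dimensional spatial
    cell-type clustering statistics along the Purkinje cell layer (adjacency
    cluster scores, run statistics, population and shell match-rate profiles)
    against seeded label-permutation nulls. Includes calibrated synthetic-data
    generators for cell maps, arbors and spiny branches so the whole pipeline
    is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
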