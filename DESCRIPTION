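Package: pigmentnet
Title: Semiempirical Forster and Exciton Modelling of Photosynthetic Pigment Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds band-resolved point-dipole Forster couplings, golden-rule
    excitation energy transfer (EET) rates and efficiencies, excitonic
    Hamiltonians with inverse-participation-ratio delocalization scoring,
    pigment-configuration perturbation experiments, and a Lambert-Beer
    solar-absorption decomposition for pigment-protein complexes such as the
    photosystem II antennae (LHCII, CP24, CP26, CP29) and the diatom
    fucoxanthin-chlorophyll protein. Pigment inventories are extracted from
    PDB/mmCIF structures; seeded synthetic generators for geometries, spectral
    libraries, site-shift tables and solar irradiance make every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
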