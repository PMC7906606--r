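Package: ThylakoidExpansion
Title: Quantitative Modelling of Thylakoid Membrane Expansion During
    De-Etiolation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the build-up of the thylakoid membrane system
    during the dark-to-light transition (de-etiolation) of Arabidopsis
    seedlings. Converts absolute galactolipid (MGDG, DGDG) and photosystem
    marker-subunit amounts (PsbA, PetC, PsaC; nmol per seedling) into membrane
    surface area per seedling via molecular footprints, with bilayer and
    envelope corrections; scales per-chloroplast morphometric surfaces from 3D
    reconstructions to the seedling level; fits four-parameter logistic growth
    curves to the surface time course, with a replicate-level mixed-effects
    variant; and compares the molecular and morphometric surface estimates.
    Includes a seeded synthetic time-course generator emulating the kinetic
    structure of de-etiolation (ER- vs plastid-pathway lipid onset, sequential
    photosystem accumulation) so every stage is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    nlme,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Lipidomics, Proteomics, TimeCourse, Regression, CellBiology
RoxygenNote: 7.3.3
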