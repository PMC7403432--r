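Package: glycomn
Title: Manganese-Related Multi-Assay Profiling: Plasma N-Glycomics,
    Trace Elements, and T2w/T1w Neuroimaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for studying manganese-related phenotypes of
    an SLC39A8 hypofunction genotype: permethylated N-glycan monoisotopic
    mass calculation and MALDI-TOF annotation against a curated 57-species
    plasma N-glycan panel, structural-category glycome statistics,
    ICP-MS trace-element method-detection-limit filtering and genotype
    comparison, and voxel-wise T2w/T1w ratio neuroimaging statistics with
    FDR control, Dunnett post-hoc tests and LDA genotype classification.
    Includes seeded synthetic-cohort generators emulating the statistical
    structure of the source study so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
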