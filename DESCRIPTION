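Package: barcodeSim
Title: Coalescent Simulation of Sample-Size Effects on DNA-Barcoding
    Polymorphism Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates single-population DNA-barcoding data under the
    constant-size Kingman coalescent with Jukes-Cantor sequence evolution,
    and quantifies how intraspecific sample size affects four estimators of
    genetic polymorphism: the mismatch distribution of pairwise distances,
    nucleotide diversity, the number of haplotypes (with Michaelis-Menten
    saturation fits to median haplotype accumulation), and the maximum
    pairwise distance. Provides the full pipeline from genealogy simulation
    through branch-length rescaling under a divergence cap, pairwise
    Jukes-Cantor distance matrices with min-max normalization, a seeded
    subsampling engine, and study-level orchestration with reproducible
    manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    S4Vectors,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'barcodeSim-package.R'
    'distances.R'
    'estimators.R'
    'genealogy.R'
    'io.R'
    'resampling.R'
    'seqsim.R'
    'study.R'
    'utils.R'
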