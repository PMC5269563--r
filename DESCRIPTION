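Package: neoepitree
Title: Cancer Neo-Epitope Trees from Tumor Somatic Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds per-tumor "cancer neo-epitope trees" from somatic
    mutation calls: population-panel filtering of germline polymorphisms,
    mutant versus wild-type peptide neo-epitope calling under an MHC class I
    binding-affinity rule, subclonal phylogeny reconstruction from variant
    read counts via binomial mixture clustering and exhaustive constrained
    tree search, permutation-null pathway-alteration enrichment with
    Benjamini-Hochberg correction, and HPV genotyping plus integration
    screening from read pairs split between host and viral references.
    Includes a synthetic-cohort generator with ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    fgsea,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
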