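Package: glycodiet
Title: Linking Glycoside-Hydrolase Gene Repertoires to Host Diet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline relating bacterial
    glycoside-hydrolase (GH) family repertoires to the diet of the host
    animal. Builds strain-by-family gene-count matrices from annotation
    tables, constructs nested prevalence-threshold family sets and selects
    a stable set by partition-agreement across hierarchical clusterings,
    scans genomic features across dietary groups with tie-corrected
    Kruskal-Wallis and Dunn post hoc tests, and quantifies phylogenetic
    signal of GH content with Blomberg's K (permutation test), Moran's I
    phylogenetic correlograms and local indicators of phylogenetic
    association (LIPA). A seeded synthetic-data generator produces Yule
    trees, Brownian-motion and white-noise traits, and diet-structured
    Poisson count matrices with tiered prevalence for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante
Config/testthat/edition: 3
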