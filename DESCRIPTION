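Package: deadwoodAssembly
Title: Community Assembly Dynamics of Saproxylic Beetles in Decomposing
    Deadwood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long-term succession of deadwood-dwelling
    beetle communities from annual emergence records: survey-design aware
    ingestion of emergence data, mixed-type trait preprocessing and Gower
    distances, phylogeny grafting and cophenetic distances, blended
    functional-phylogenetic distances with a tip-shuffling null model
    yielding standardized effect sizes of mean pairwise distance, negative
    binomial and Gaussian additive trend models with spatial smooths,
    blend-weight model selection and leave-one-trait-out ablation,
    compositional succession analysis (NMDS, PERMANOVA and a conditional
    inference tree over ordination scores), temporal niche statistics, and
    a synthetic community generator with known ground truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    jsonlite,
    MASS,
    mgcv,
    phytools,
    stats,
    utils,
    vegan
Suggests:
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
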