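Package: engraftr
Title: Donor-Microbiota Engraftment Tracking and Community Statistics for
    Microbial Transplantation Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing amplicon sequence variant (ASV) count
    tables from microbiota transplantation experiments. Classifies donor
    inoculum ASVs as unique or common relative to recipient baseline
    communities, tracks engraftment of donor-unique ASVs in recipients,
    and contrasts engraftment success with Fisher's exact test.
    Includes first-principles implementations of the community-ecology
    statistics such studies use (rarefaction, alpha diversity with
    Kruskal-Wallis and Dunn post-hoc tests, Bray-Curtis dissimilarity,
    principal-coordinate analysis, PERMANOVA, beta-dispersion) and
    microbiome-metabolome integration (PLS-DA with VIP scores, Spearman
    correlation with FDR control, symmetric Procrustes with PROTEST),
    plus a seeded synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
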