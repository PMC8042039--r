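Package: climorph
Title: Climate-Associated Midfacial Shape via Geographically Weighted
    Reduced-Rank Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric analysis of climate-associated midfacial
    shape in worldwide human cranial samples. Provides generalized Procrustes
    superimposition, object-symmetry symmetrization, thin-plate-spline
    imputation of missing landmarks, sex-dimorphism correction, and centroid
    size partitioning into anatomical regions; a reduced rank regression of
    group mean shape on climate variables with a geographic-similarity weight
    matrix as a generalized-least-squares error structure; projection of
    individual specimens (including out-of-sample fossils) into the resulting
    adaptive shape space; and a synthetic-data generator with known ground
    truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
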