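Package: nbbd
Title: Network-Based Biomarker Discovery from Microbiome Abundance Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers phenotype-specific microbial ecology networks from OTU
    abundance tables (k-nearest-neighbour proximity graphs, SparCC basis
    correlations, Meinshausen-Buhlmann neighbourhood selection, and random
    matrix theory thresholding), scores taxa by differential node topology
    between the two phenotype networks or by membership in shared critical
    attack sets derived from graph resilience measures (vertex attack
    tolerance, integrity, tenacity), combines network scores with random
    forest feature importance in a hybrid ranking, and evaluates selected
    taxa with a random forest classifier harness over nested
    feature-selection subsets. Includes a synthetic benchmark generator
    with planted differential network structure, compositional counts and
    zero inflation, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    glmnet,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
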