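Package: consensusprio
Title: Consensus Disease-Gene Prioritization with Early-Recognition Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consensus prioritization of disease genes from case/control
    expression matrices. Combines three independent evidence streams --
    moderated-t differential expression with Benjamini-Hochberg control,
    a machine-learning stage (minimum-redundancy maximum-relevance
    reduction, a ranker ensemble and a validity-filtered classifier panel
    fused through desirability functions), and weighted gene co-expression
    network modules -- by set intersection followed by minimum/mean rank
    fusion. Ships the statistical validation layer (hypergeometric
    upper-tail test, bootstrap resampling null with fold-enrichment,
    Wilcoxon signed-rank comparison of rankings) and early-recognition
    evaluation metrics transplanted from virtual screening (AUAC, ROC
    area, enrichment factor, RIE and BEDROC over randomized-tail
    evaluation rankings), plus a synthetic-data generator with planted
    differential expression and co-expression modules for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    fgsea,
    jsonlite,
    limma,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
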