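Package: cofosnet
Title: Co-Activation Network and Microcircuit Path Analysis for Regional
    c-Fos Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds signed, significance-thresholded Spearman co-activation
    networks from per-animal regional c-Fos cell counts and characterizes
    them with graph-theoretical metrics (degree, strength, betweenness,
    global efficiency, transitivity, Louvain modularity with bootstrap-based
    resolution selection), hub detection against diagonal-preserving shuffle
    null ensembles, random/lattice normalization, and permutation-based
    network comparisons. Also fits a Bayesian path (mediation) model of the
    dentate-gyrus excitatory/inhibitory microcircuit with convergence and
    fit diagnostics (R-hat, posterior predictive p, DIC/WAIC/LOOIC),
    standardized direct/indirect/total effects, multigroup comparisons, and
    provides novel-object-recognition discrimination indices, effect sizes,
    and a synthetic-data generator emulating the assumed data structure.
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
    igraph,
    purrr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
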