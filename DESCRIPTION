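Package: commtraj
Title: Multilayer Community Trajectories for Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects communities in multiplex (multilayer) gene networks by
    greedy modularity optimization under a single shared partition, sweeps the
    modularity resolution parameter to build per-gene community trajectories,
    and clusters trajectories by Hamming distance. Patients are stratified by
    selecting, for each patient, the minimal sets of altered genes that stay
    together along their trajectories (persistence parameter theta) in groups
    of bounded size (parameter lambda), followed by Jaccard similarity, Ward
    hierarchical clustering and PAM-guided cluster-number selection. Includes
    shuffle-based null and recursive gene-exclusion robustness analyses,
    multiscale-bootstrap and Monte Carlo cluster-confidence procedures, a
    network enrichment analysis test (NEAT) for per-layer link enrichment, and
    generators for planted-structure multiplex networks and synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
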