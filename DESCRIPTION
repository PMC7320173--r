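Package: gutnet
Title: Bipartite Organism-Compound Interaction Networks for the Gut Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, validating and analysing literature-curated
    bipartite networks that link gut microbes (and host cells) to the
    small-molecule metabolites they import or export and the macromolecules
    they degrade. Provides a JSON dialect reader/writer for curated network
    resources, construction operations (strain consolidation, degradation
    product propagation, network merging), prevalence-based species selection
    from metagenome abundance tables, bipartite degree statistics with
    maximum-likelihood exponential and truncated power-law fits, a
    permutation test of microbiome-metabolome concordance between metabolite
    producers and measured metabolite levels, and seeded generators of
    synthetic networks and paired abundance/metabolome experiments for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
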