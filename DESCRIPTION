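Package: dispersalshare
Title: Shared-Taxa Dispersal Analysis for Paired Human and Doormat Microbiomes
Version: 0.1.0
Authors@R:
    person("Dispersalshare", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers bacterial dispersal potential in the human living
    environment from the proportion of amplicon sequence variants (ASVs)
    shared between human samples (saliva, skin, feces) and paired indoor
    doormat samples. Provides I/O for ASV count tables (plain TSV and mothur
    'shared' dialects), the post-classification filtering chain (lineage
    blacklist, global singleton removal, strict negative-control ASV
    removal), hypergeometric rarefaction, shared-taxa statistics and Venn
    partitions, community-distance machinery (Bray-Curtis, Sorensen,
    Hellinger; PCoA, PERMANOVA, PERMDISP) implemented from first principles,
    binomial random-intercept GLMMs with a p-gated then AIC-gated forward
    selection protocol and simulation-based residual diagnostics, and a
    generative simulator of paired human/doormat studies with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
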