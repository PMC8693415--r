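Package: gutassembly
Title: Community Assembly Analysis for Gut Microbiome Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the balance between stochastic and deterministic
    ecological processes shaping microbial communities from OTU count
    tables, a rooted phylogeny and sample metadata. Implements alpha and
    beta diversity, principal-coordinate ordination with permutation tests
    (PERMANOVA, MRPP, PERMDISP), phylogenetic null models (NTI, betaNTI),
    Bray-Curtis based Raup-Crick null deviations, the five-process
    ecological partitioning of community turnover (variable selection,
    homogeneous selection, dispersal limitation, homogenizing dispersal,
    drift), the normalized stochasticity ratio (NST), and Spearman
    co-occurrence networks. Includes a synthetic community generator that
    simulates assembly under known regimes, from neutral drift to
    phylogenetically conserved habitat filtering, so that assembly
    inference can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
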