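Package: phantomepi
Title: Genealogical Assessment of Phantom Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the genealogical evidence that a reported SNP-by-SNP
    interaction is phantom epistasis, i.e. the footprint of an unobserved
    purely additive causal variant. Given an ancestral recombination graph
    (ARG) in tree-sequence table form and a recombination map, the package
    enumerates clades and their genomic spans, computes the conditional
    association between each clade's carrier genotype and the interaction
    term, and reports the minimum effect size an omitted variant would need
    in order to explain the observed interaction (Tests 1A/1B), together
    with a per-position profile of evidence against unobserved problematic
    clades (Test 2). Includes a neutral-coalescent clade-probability null,
    a sequentially Markov coalescent simulator with recombination, and a
    scaled simulation study (phantom versus true epistasis, LD-pruned
    interaction scan, ROC evaluation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
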