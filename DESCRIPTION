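Package: treesignal
Title: Phylogenetic Signal in Ecological Traits over Posterior Tree Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates phylogenetic signal in continuous and binary species
    traits with Blomberg's K (randomization test, optional measurement-error
    model) and Pagel's lambda (maximum likelihood with likelihood-ratio test;
    an equal-rates Mk pruning likelihood for binary traits), and propagates
    phylogenetic uncertainty by repeating every test across a posterior sample
    of ultrametric trees, summarising per-trait distributions of statistics
    and p-values. Includes derivation of species-level traits from raw
    survival and feeding-trial records (log-rank screening, control-adjusted
    consumption, mixed-model feeding rates with zeroing rules) and simulators
    for every input: pure-birth trees, Brownian-motion and Mk traits,
    perturbed tree samples, and raw experiment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    survival,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
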