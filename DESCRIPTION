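Package: aopke
Title: Causal Key-Event Networks and Bayesian Transcriptomics for Adverse
    Outcome Pathway Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether an Adverse Outcome Pathway Key Event is
    active in a chemical exposure from liver transcriptomics. Represents the
    regenerative-proliferation Key Event as a signed causal subnetwork of
    genes, proteins and processes; answers conditional-independence
    (d-separation) queries and identifies events sufficient to infer the
    outcome; calls differential expression with a hierarchical Bayesian
    shrinkage model and a region-of-practical-equivalence (ROPE) decision
    rule on 95% highest-density intervals; and overlays gene-level calls on
    the network to report Key-Event activation per dose and sacrifice time.
    Includes a synthetic-data generator emulating the Open TG-GATEs rat
    liver study design so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    igraph,
    jsonlite,
    limma,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
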