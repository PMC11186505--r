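Package: otoscreen
Title: Transcriptome Connectivity Screening, Kinome Random-Sampling
    Analysis and Perilymph Pharmacokinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in silico drug-repurposing workflow for noise-induced
    hearing loss. Calls differentially expressed genes between two
    cochlear conditions, ranks biological pathways by hypergeometric
    enrichment FDR, queries a drug-perturbation signature compendium in
    mimic or reverse mode with signed overlap and cosine scores,
    aggregates per-pathway drug hits into a cross-dataset consensus,
    deconvolves kinome peptide-array kinetics into upstream-kinase
    random-sampling z-scores, and computes non-compartmental
    pharmacokinetic parameters from perilymph concentration-time
    profiles. Ships a synthetic-data module that generates every input
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
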