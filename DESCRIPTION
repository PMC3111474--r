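Package: tnevo
Title: Evolutionary Modeling of Transcription-Network Rewiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint probabilistic inference of transcription-factor target
    relationships across species. Regulatory states of orthologous genes
    evolve along a phylogeny as a two-state continuous-time Markov chain;
    promoter sequences are scored against a binding motif (PSSM) through a
    scan-based likelihood, and gene-expression cluster memberships through
    target and background multinomials. Parameters are estimated by EM on
    the weighted joint likelihood, regulatory states are inferred by
    maximum a posteriori decoding, and network rewiring is quantified with
    conservation categories, permutation nulls built from shuffled motifs,
    and a simulation/cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
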