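Package: bitterevo
Title: Evolutionary Analysis of Strychnine Recognition by Bitter Taste
    Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing how ligand recognition evolves in G
    protein-coupled receptor families, built around the strychnine-sensing
    bitter taste receptors T2R10 and T2R46. Provides amino-acid substitution
    models and Felsenstein pruning likelihoods, marginal and joint ancestral
    sequence reconstruction with per-site posterior probabilities,
    RelTime-style relative divergence times and lineage rates, counting-based
    site-specific dN/dS estimation on codon alignments, Ballesteros-Weinstein
    numbering of alignment columns, a mutagenesis-grounded rule engine that
    classifies sequences as strychnine binders, sequence simulators with
    recorded ancestral truth, and an end-to-end pipeline with a command-line
    front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
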