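Package: spliceDrift
Title: Weak Selection and Drift Load at Splice Sites from Substitution Patterns
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers weak negative and positive selection acting on splice-site
    consensus (Cn) and nonconsensus (Nc) nucleotides from interspecies
    substitution patterns. Ancestral states are reconstructed by maximum
    parsimony over a reference/sister/outgroup triplet, Cn-to-Nc and Nc-to-Cn
    substitution frequencies are contrasted with nucleotide-matched neutral
    controls, and the population-scaled selection coefficient 4Nes is recovered
    by numerically inverting the Kimura fixation-rate ratio S/(1 - exp(-S)).
    Also provides a multispecies conservation-depth statistic with
    column-bootstrap confidence intervals, drift-load summaries, and a bundled
    origination-fixation sequence-evolution simulator with known ground-truth
    selection for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, Software
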