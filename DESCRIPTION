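Package: mycohet
Title: Comparative-Genomic Signatures of Mycoheterotrophy in Orchids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the comparative-genomics computations
    used to characterise mycoheterotrophic plant genomes: F-index
    classification of gene-family loss from orthogroup count matrices,
    reciprocal-best-hit ortholog detection with NG86 synonymous-substitution
    (Ks) estimation, kernel-density mode estimation of Ks distributions with
    bootstrap confidence intervals and outgroup relative-rate decomposition,
    Jukes-Cantor dating of LTR retrotransposon insertions, one-sided
    hypergeometric enrichment with Bonferroni correction, and k-mer based
    genome-size estimation. A synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
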