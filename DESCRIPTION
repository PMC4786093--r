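Package: codonfit
Title: Fitness Effects of Synonymous Codon Usage in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the selective value of synonymous codon usage
    bias in highly expressed bacterial genes. Implements synonymous allele
    design with a protected N-terminal prefix, relative synonymous codon
    usage (RSCU) and relative adaptiveness from a highly expressed reference
    gene set, a tRNA-abundance model of the increase in translation time,
    anti-Shine-Dalgarno hexamer affinity scanning, selection-coefficient
    estimation from serial-transfer competition trajectories (outlier
    filtering, dye-swap normalization, group comparison), the multiplicative
    per-codon fitness decomposition with its regression and correlation
    analyses, qPCR-based relative mRNA quantification and half-life
    estimation, and a synthetic-data generator so the whole pipeline can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
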