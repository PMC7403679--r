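Package: nichescan
Title: Three-Population Divergence Scans and Reaction-Norm Analysis for
    Burying-Beetle Local Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic divergence scans for a
    two-focal-population plus outgroup design: Hudson and Weir-Cockerham
    F_ST in tiled or sliding windows, population branch statistics (PBS),
    z-standardised outlier detection, nucleotide diversity and Tajima's D,
    per-gene divergence scoring and ranked gene-set enrichment
    (ES/NES/FDR by gene-label permutation). Includes a Balding-Nichols
    synthetic-data generator for three diverged populations with planted
    selected loci, a GATK-style hard filter for VCF records, and the
    phenotype computations used in burying-beetle breeding experiments:
    egg volume, carcass-use efficiency, clutch-size reaction norms with
    elevation/slope permutation contrasts, and guild relative-abundance
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
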