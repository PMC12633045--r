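Package: sdsup
Title: Census and Mapping of Segregation Distorter Suppressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference pipeline for surveying suppressors of the selfish
    Segregation Distorter (SD) chromosome in inbred Drosophila panels:
    Responder (Rsp) satellite copy-number estimation from sequencing read
    depth, slot-blot signal and qPCR standard curves, with a PCA composite
    score; drive-strength (k) quantification from cross offspring counts with
    replicate filtering and count pooling; reciprocal-cross classification of
    X-linked and autosomal suppressors; chromosome-level suppressor frequency
    estimation with bootstrap intervals; a covariate-adjusted per-SNP linear
    association scan with Bonferroni thresholds; and recombination mapping of
    an X-linked suppressor by minimum-discordance interval inference, with a
    haplotype-based candidate SNP filter. A synthetic-data module emulates
    every input class so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
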