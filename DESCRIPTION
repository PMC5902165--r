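Package: circamyo
Title: Circadian Rhythm Detection in Human Skeletal Muscle Transcriptomes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects circadian rhythms in bulk RNA-seq time courses from
    human skeletal muscle using two complementary frameworks. For in vivo
    designs (several donors sampled around the clock) it fits a harmonic
    regression with a donor random intercept separately to intronic
    (pre-mRNA) and exonic (mRNA) signal, tests rhythmicity by likelihood
    ratio, classifies genes as rhythmic at the transcriptional and/or mRNA
    level, derives an exon/intron half-life proxy, and tests phase-binned
    motif enrichment. For dense in vitro time courses (synchronized
    myotubes, with and without CLOCK knockdown) it classifies expression
    curves via LOESS-derived shape features and a self-trained random
    forest, assigns genes to the 16 combinatorial rhythmicity models over
    donors and conditions, and quantifies amplitude blunting. A synthetic
    data generator reproduces both study designs with known ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    rtracklayer,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    lme4,
    edgeR,
    jsonlite,
    optparse
Config/testthat/edition: 3
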