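Package: ucevar
Title: Constraint Analysis of Sequence Variants in Ultraconserved Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses of natural sequence variation inside ultraconserved
    elements (UCEs). Variants are stratified by minor allele frequency into
    rare, intermediate and prevalent classes and their per-base conservation
    scores (phyloP-style) are compared against G/C-composition-matched
    random positions drawn from the element universe, with bootstrap
    confidence envelopes around empirical distribution functions and
    Kolmogorov-Smirnov tests. Overlap of variant positions with regulatory
    feature tracks (e.g. clustered transcription-factor binding sites) is
    tested by Pearson chi-squared contrasts against matched nulls and by
    repeated fixed-size resampling with Mann-Whitney comparisons. Includes
    interval algebra (merge, overlap, length-preserving shuffles) on BED
    style half-open coordinates, pooled-sequencing design arithmetic, a
    fully seeded synthetic-data generator (genome, score track, element,
    feature and variant sets) so the entire pipeline runs without external
    downloads, and an orchestration layer that writes machine-readable
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    methods,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
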