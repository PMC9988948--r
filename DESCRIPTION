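Package: refqual
Title: Multi-Species Quality Evaluation of Reference Genomes and Gene Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores reference genomes and their gene annotations across a cohort
    of species using ten scaled quality indicators derived from assembly
    statistics (genome-size-adjusted contig/scaffold N50 percentiles, spanned-gap
    rate), RNA-seq read-mapping summaries (unique/overall/multi-mapping rates and
    their mean, the mapping quality index MQI), read-quantification summaries
    (assignment success and failure rates and their mean, the quantification
    quality index QQI), and a PCA-based transcript-diversity metric computed from
    gene-biotype proportions. The indicators combine into a weighted NGS
    applicability index that ranks species by how amenable their reference
    resources are to short-read sequencing applications. Includes parsers for
    the standard summary artifacts (assembly statistic tables, HISAT2-style
    alignment summaries, samtools-stats reports, featureCounts assignment
    summaries, GTF annotations) and a synthetic-cohort generator with
    controllable latent quality and diversity gradients for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan
Config/testthat/edition: 3
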