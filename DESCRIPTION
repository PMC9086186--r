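Package: mutburden
Title: Mutation Burden Analysis for Chemical Mutagenesis Genome Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating mutagen-induced mutation load from
    multi-sample whole-genome resequencing variant calls, as used in
    EMS (ethyl methanesulfonate) mutagenesis screens. Variants are keyed
    by (CHROM, POS, REF, ALT, GENO) so that mutation types shared with an
    untreated control panel can be removed, leaving group-specific
    mutations; these are annotated against gene models (exonic, intronic,
    upstream, intergenic; synonymous, nonsynonymous, stopgain, stoploss)
    and summarised into per-sample and per-group burden statistics:
    clean-base-normalised mutation rates, transition/transversion ratios,
    class percentages, and group comparisons (normality- and
    variance-gated t tests, ANOVA with Tukey HSD). Also included are
    hypergeometric over-representation tests with Benjamini-Hochberg
    correction for generic gene-to-term maps, a phenotype-exclusive
    nonsynonymous-gene screen, and a truth-annotated synthetic cohort
    generator (genome, gene models, shared polymorphism pool, per-sample
    VCFs) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    car,
    nortest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
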