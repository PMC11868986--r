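Package: regsnap
Title: Regulatory Mechanism Mapping for GWAS Risk Loci via Allele-Specific
    Transcription Factor Binding Disruption
Version: 0.1.0
Authors@R:
    person("regsnap", "developers", email = "regsnap@example.org",
           role = c("aut", "cre"))
Description: Tools to map genome-wide association study (GWAS) risk loci to
    candidate regulatory mechanisms. Index SNPs are expanded into linkage
    disequilibrium (LD) sets from haplotype panels; position weight matrices
    (PWMs) are discovered de novo from top ChIP-seq peaks against
    dinucleotide-shuffled backgrounds with false discovery rate control and
    matched to a motif database; allele-specific best-match PWM scores with
    affinity and rank p-values identify transcription factor
    binding-disrupting SNPs; brain eQTL summary statistics and regulatory
    annotations are integrated to score and rank candidate causal variants.
    A synthetic-data module generates every pipeline input with planted
    ground truth so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings,
    VariantAnnotation,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
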