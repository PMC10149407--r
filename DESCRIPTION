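Package: hsp90regulon
Title: Strain-Specific Hsp90-Dependent Transcriptional Regulation from
    RNA-Seq and Promoter Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription factors (TFs) whose regulons show
    strain-specific expression responses to Hsp90 inhibition. Implements
    negative-binomial differential expression with fold-change cutoffs,
    classification of strain-pair-specific genes into buffered and
    potentiated classes, cross-strain promoter scanning with
    position weight matrices and conservation classification of binding
    sites, a Kruskal-Wallis / Wilcoxon / two-proportion enrichment cascade
    that nominates candidate TFs, chaperone-client and GO term enrichment,
    and genetic (TN93) and expression distance trees built with BIONJ.
    Ships a synthetic-data generator that emulates the five-strain,
    two-condition, three-replicate study design with planted TF regulons,
    so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
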