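Package: panelscreen
Title: Tumor/Normal Targeted-Capture Mutation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic mutation screening of paired
    tumor/normal targeted-capture sequencing panels. Classifies paired
    variant calls into high- and low-confidence somatic variants with
    GATK-style hard filters, categorizes variant effects against gene
    models, matches calls to a COSMIC-style somatic mutation catalogue
    with exact and loose (position-shifted, split multi-nucleotide)
    criteria, computes strand-collapsed substitution spectra and
    trinucleotide-context mutation frequencies with composition-normalized
    coding versus non-coding enrichment statistics (odds ratios, Woolf
    confidence intervals, Bonferroni adjustment), and derives gene-level
    copy-number calls from windowed tumor/normal coverage ratios. A
    self-contained synthetic-cohort generator emits panels, paired VCFs,
    coverage tracks and ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
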