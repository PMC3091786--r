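Package: pdzome
Title: Post-Processing of Domain-Centered Yeast Two-Hybrid Interactome Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for domain-centered yeast two-hybrid (Y2H)
    interactome screens against PDZ-domain baits: builds a PDZ-domain catalog
    from multiple annotation sources and designs Gateway-tailed cloning
    primers, quality-filters prey sequencing traces by a sliding-window PHRED
    criterion, identifies prey clones and determines their reading frame by
    local alignment at the activation-domain fusion junction, classifies
    protein C-termini into PDZ-binding consensus classes (including the
    conservative splice-form rule, B2-tailed and C-terminally truncated
    constructs, and minimal interacting regions), and assembles the
    bait-prey network with promiscuity, coverage, class-proportion, overlap
    and pooling statistics plus GraphML/SIF export. A synthetic-data module
    generates toy proteomes, planted bait domains and simulated screen reads
    with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
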