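Package: butqPCR
Title: Degenerate Primer Panels and qPCR Quantification of the Gut
    Butyrate Synthesis Gene but
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the butyrate synthesis capacity of the
    human gut microbiome by quantitative PCR of the bacterial
    butyryl-CoA:acetate CoA-transferase (but) gene. Implements IUPAC
    ambiguity-code algebra for degenerate oligonucleotides,
    phylogeny-guided design of degenerate primer pairs by recursive
    descent over a clade tree, degenerate in-silico PCR for amplicon
    prediction and local off-target screening, delta-Ct relative
    quantification against a spike-in (C. elegans UNC-6) or 16S rRNA
    gene reference, and the accompanying statistical toolkit
    (Mann-Whitney group comparison, Spearman correlation, Bland-Altman
    method agreement, centred log-ratio transformation of compositional
    count tables with multiplicative zero replacement). Ships the
    curated 36-taxon target table and the six-cluster primer panel as
    machine-readable fixtures, plus synthetic-data generators with known
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'iupac.R'
    'AllClasses.R'
    'quant.R'
    'AllGenerics.R'
    'panel.R'
    'phylo.R'
    'design.R'
    'insilico.R'
    'stats.R'
    'synthetic.R'
    'cli.R'
    'butqPCR-package.R'
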