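Package: alleleReg
Title: Canonical Allele Registration, Normalization and Cross-Referencing of
    Genetic Variants
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale registry for nucleotide variants. Parses and
    validates HGVS expressions and VCF records against reference sequences,
    trims and left-/right-aligns indels, projects transcript variants onto a
    primary genome assembly through CIGAR-encoded alignments, and groups all
    equivalent contextual alleles under persistent canonical allele
    identifiers (CAids) with active/inactive merge semantics. Computes amino
    acid consequences of coding variants on the fly to group nucleotide
    variants with identical alternate protein sequences, deduplicates VCF
    streams by canonicalization, mines assertion and allele-frequency tables
    for discordance among same-protein-effect variants, and layers external
    links over registered alleles via RFC 6570 URI templates. Ships a
    deterministic synthetic fixture generator (toy assembly, multi-exon
    transcripts on both strands, planted repeat tracts and variant sets) and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
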