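# alleleReg

Globally aggregating information about a genetic variant requires knowing
when two records describe the same variant — and the same indel can be
spelled many ways: against different transcripts, shifted left or right
through repetitive sequence, with or without redundant flanking bases.
`alleleReg` is a desk-scale registry for nucleotide variants that solves
this by *canonicalization*: every input (HGVS expression or VCF record) is
validated against its reference sequence, trimmed to minimal form,
projected through CIGAR-encoded transcript alignments onto a primary
assembly, left-aligned there, and grouped with all equivalent spellings
under one persistent canonical allele identifier (CAid). It is written for
anyone who needs variant identity at the level clinical genetics requires
— curators deduplicating a callset, tool authors cross-referencing
assertion tables, method developers who need a compact, fully inspectable
registry core.

## The model in brief

A **contextual allele** is the 4-tuple (reference, interval, reference
allele, alternate allele) in zero-based half-open interbase coordinates:
`[4,5)` is the 5th base, `[4,4)` the insertion point after it. Trimming
and shifting generate the equivalence class of spellings on one reference;
the maximally 5′ spelling (**left-aligned**) on the primary assembly is
the grouping key, while emitted HGVS follows the 3′ rule. A **canonical
allele** is the group of all contextual alleles across references with
that key, named `CA<n>`, persistent under merges (the losing identifier
goes inactive but stays dereferenceable via `replaced_by`). Amino acid
consequences are computed on the fly by translating the CDS before and
after the edit, and nucleotide variants with an identical alternate
protein sequence are grouped — the basis for mining discordant
pathogenicity assertions and discordant allele frequencies. External
sources attach links through RFC 6570 level-1 URI templates.

## Worked example

A deletion inside the trinucleotide tract of `AGTTCACTGCTGCTGCATCA`:

```r
library(alleleReg)
db <- refdb("R3", list(ref_record("R3", "genomic-primary",
                                  seq = "AGTTCACTGCTGCTGCATCA")))
a <- parse_hgvs(db, "R3:g.10_12del")
normalize_allele(db, a)
#> <normalized allele>
#>   minimal:       R3:[9,12):CTG>
#>   left-aligned:  R3:[6,9):CTG>
#>   right-aligned: R3:[13,16):TGC>
#>   shift range:   [6,13]
length(enumerate_equivalents(db, a))
#> [1] 8
```

The deletion can sit at any of eight anchors (interbase 6 through 13); all
eight apply to the same alternate sequence. The left-aligned form
`[6,9):CTG` is the canonical key, so registering the leftmost and the
rightmost spelling yields one identifier:

```r
reg <- allele_registry(db)
register_allele(reg, "R3:g.7_9del")   # "CA1"
register_allele(reg, "R3:g.14_16del") # "CA1"
```

On the bundled synthetic assembly (a 420-codon coding transcript with ATG
at codon 246), two different substitutions in that codon produce the same
protein:

```r
spec <- fixture_spec(seed = 1)
bundle <- make_reference_bundle(spec, tempfile("registry-demo"))
protein_consequence(bundle$db, parse_hgvs(bundle$db, "TXCOD1:c.736A>C"))
#> <protein effect> TXCOD1 substitution p.Met246Leu
protein_consequence(bundle$db, parse_hgvs(bundle$db, "TXCOD1:c.736A>T"))
#> <protein effect> TXCOD1 substitution p.Met246Leu
```

and deduplicating the generated 1003-record variant stream recovers
exactly the planted structure:

```r
sets <- make_variant_sets(spec, bundle)
rep <- find_duplicates(bundle$db, sets$vcf)
#> 1003 records read, 1000 processed, 3 skipped, 50 duplicates
```

A command-line wrapper with `register`, `query`, `normalize`, `dedup`,
`links-*`, `mine-*` and `make-fixtures` subcommands is installed at
`system.file("cli", "allelereg", package = "alleleReg")`.

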