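---
title: "Canonical allele registration: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical allele registration: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleReg)
```

## The problem

The same nucleotide variant can be written in many ways: against different
transcripts, against the genome, shifted left or right through repetitive
sequence, with or without redundant flanking bases. Aggregating information
about a variant across databases therefore needs a representation that is
independent of any particular reference sequence and any particular
spelling. This package provides that representation: every *contextual
allele* — a variant anchored to one reference — is normalized within its
reference, projected onto a primary assembly, and grouped with all its
equivalents under one persistent canonical identifier (CAid).

## The allele model

A contextual allele is the 4-tuple (reference sequence, interval, reference
allele, alternate allele). All intervals are zero-based, half-open,
interbase: `[4,5)` is the fifth base and `[4,4)` is the insertion point
between the fourth and fifth bases. This convention makes insertions
first-class (a zero-length interval) and makes interval arithmetic
closed under trimming and shifting; conversion to and from 1-based
inclusive numbering happens only at the HGVS boundary.

Four variant categories are distinguished — substitution, insertion,
deletion, indel — with duplications treated as a special insertion (the
duplicated span inserted at its 3′ edge) and inversions as a special indel
(delins of the reverse complement). Nucleotide and protein variants are
different kinds of entity related one-to-many: a transcript allele induces
at most one alternate protein sequence, while one protein change may arise
from many nucleotide variants.

## Normalization

Two operations generate equivalent spellings:

* **Trimming** removes bases shared by the reference and alternate alleles,
  first from the left, then from the right, shrinking the interval. The
  result is the *minimal* representation.
* **Shifting** moves a pure insertion or deletion through repetitive
  context one base at a time, without changing the alternate sequence a
  spelling produces. The maximally 5′ spelling is *left-aligned*, the
  maximally 3′ one *right-aligned*; `enumerate_equivalents()` lists the
  whole contiguous family.

Every shift is checked against the invariant that applying the edit
reproduces a character-identical alternate sequence; the test suite
verifies this on 10,000 random indels and checks the enumeration against
an exhaustive search on references up to 50 bp.

The **left-aligned** form is the internal grouping key. Emitted HGVS for
shiftable indels follows the right-aligned (3′ rule) placement, matching
community convention; the two choices are independent and deliberate.

## Reference database and coordinate projection

Non-primary references (transcripts, other assemblies) are stored as
transformations of the primary assembly: a target locus, a CIGAR over
`M`/`I`/`D`, the sequences of inserted or substituted runs in CIGAR order,
and unaligned 5′/3′ tails. Reconstruction walks the CIGAR over the target
slice, reverse-complements for minus-strand transcripts, and attaches the
tails. For transcripts, `D` runs are introns and the exon structure is
derived from the alignment; a CDS interval (transcript coordinates, a
positive multiple of 3) supports `c.` numbering and translation.

Projection maps transcript intervals to the primary assembly and back.
Nonzero-length intervals must sit inside one unedited match run — a
variant overlapping an insertion, deletion or substituted run has no
faithful genomic image and raises an `areg_unprojectable` error rather
than guessing. Zero-length insertion anchors at an exon–exon junction are
ambiguous between the two flanking exons; they resolve to the genomic
interbase point at the 3′ end of the upstream exon *in transcript
orientation* (on the plus strand the intron's left edge, on the minus
strand its right edge). This fixed rule keeps canonicalization
deterministic. Intron offsets (`c.N+k`, `c.N−k`) resolve to the genomic
base `k` into the intron from the donor/acceptor side of the anchor,
strand-aware, and are rejected if they do not land inside an intron.

## Canonicalization and the registry

`canonicalize()` trims the allele, projects it onto the primary assembly
(reverse-complementing the alleles for minus-strand transcripts), and
left-aligns there; the resulting genomic spelling is the canonical key.
Genomic left-alignment wins over transcript-level alignment when the two
disagree at a splice boundary — this is what makes an intronic spelling
(`c.N−1delG`) and an exonic spelling (`c.NdelG`) of a deletion inside a
G run that spans the acceptor meet at one key. Alleles on references with
no alignment still register, under a reference-local key flagged
non-canonicalizable; refusing them would break batch registration.

The registry issues `CA<n>` identifiers from a monotone counter, never
reissuing one. Merging marks the loser inactive with `replaced_by`
pointing at the winner and re-points all indices; the inactive record and
its members remain dereferenceable forever. When two merge candidates are
both active, the lower-numbered CAid stays active (an arbitrary but
deterministic choice). Splitting is operator-invoked: the old record is
deactivated, each member group re-registers under a fresh CAid, and
`replaced_by` points at the successor holding the member majority — the
trigger conditions for splits are environmental (alignment or assembly
updates) and are not automated here. The store serializes to canonical
JSON (records sorted by CAid, indices by key) so save/load round-trips are
byte-identical.

## Protein consequences

Amino acid sequences are never stored: the CDS is translated before and
after applying the nucleotide allele (standard nuclear code, stopping at
the first stop codon; for frameshifts the alternate is translated past the
annotated CDS end so a novel stop can be found). The two proteins are
diffed by stripping common prefix and suffix. A one-residue difference is
a substitution (`p.Met246Leu` style, three-letter codes, output-only); a
difference spanning fewer than eight residues gets a compact descriptor;
anything wider, a change straddling the CDS start, a lost stop with no
nearby replacement, or a change running into an incomplete terminal codon
is reported as `out-of-window` without a descriptor. Grouping of variants
with the same protein effect keys on the *full alternate protein
sequence*, not the descriptor text, so identical descriptors in different
genes never collapse, and the grouping scope needs no per-gene bookkeeping.

One consequence of sequence-level keying worth knowing: all synonymous
variants of one protein share its reference sequence as their "alternate"
protein, so the mining inputs deliberately avoid synonymous records.

## Link layering

External sources register an RFC 6570 URI template for their API and
optionally their UI, plus the parameter names they will attach per CAid.
Only level-1 simple string expansion (`{var}`) is accepted — every
substitution the registry needs is a plain one — and values are
percent-encoded over their UTF-8 bytes, passing only unreserved
characters. A PUT record (possibly with no parameters, for sources whose
URIs use the CAid alone) marks that the source has content for an allele;
links survive merges because reads resolve the queried CAid through
`replaced_by` and collect records attached to any CAid of the merged
family, expanding templates with the active identifier.

## Mining

* **Deduplication**: every record of a stream is canonicalized; records
  sharing a key form a duplicate group and the duplicate count is
  processed minus distinct. Invalid records are skipped and counted, never
  fatal, and the report is invariant under input permutation.
* **Assertion discordance**: five classification levels collapse to three
  (likely-benign with benign, likely-pathogenic with pathogenic); for
  every unordered pair of distinct nucleotide variants with an identical
  alternate protein, the (more severe, less severe) cell of a 3×3
  lower-triangular matrix is incremented. Pairs, not groups, populate the
  cells; a group-level report and a per-variant tally are emitted
  alongside, since the two counting units answer different questions. A
  variant carrying conflicting assertions keeps the most severe one.
* **Frequency discordance**: among same-protein-effect groups, those whose
  lowest allele frequency is below 1% and highest above 5% (both
  configurable) are reported — the spread that would produce conflicting
  classification evidence codes.

Database-scale counts of this kind depend on third-party dumps and are out
of scope; the package's claims are about the mechanisms, demonstrated on
generated inputs with planted truth.

## The synthetic fixtures

`fixture_spec()` fixes the study conditions; `make_reference_bundle()` and
`make_variant_sets()` realize them deterministically from one seed (same
seed, byte-identical files). The defaults are: an 8 kb toy assembly; a
plus-strand 3-exon coding transcript of 420 codons with ATG planted at
codon 246 and at a reserved run of codons (each planted ATG supports a
Met→Leu pair — two different substitutions, one alternate protein); a
minus-strand coding transcript; a transcript whose acceptor site sits
inside a four-base G run; three same-gene transcripts at staggered starts
differing at `c.5`; a tailed transcript and an unaligned verbatim
reference; CTG×4 and A×6 repeat tracts. The variant stream holds 1000
valid records of which 50 pairs are left-/right-aligned spellings of the
same homopolymer deletion, plus 3 reference-mismatch records; the
assertion table plants 3 benign–uncertain and 2 uncertain–pathogenic
discordant pairs, 5 concordant pairs and the codon-246 pair (uncertain vs
likely-pathogenic); the frequency table holds 100 pairs of which 4 cross
both thresholds (0.005/0.06 against 0.02/0.04). Pair sizes of two per
group keep the bookkeeping exact.

What the generator does *not* emulate: realistic human genome composition,
mismatching transcript alignments (substituted runs are exercised only in
unit fixtures), multi-allelic sites, and variants affecting splicing —
the model assumes a variant is the same change at genome and transcript
level, so a substitution that alters splicing is outside the registry's
canonicalization model altogether. Passing tests therefore demonstrate
the correctness of the machinery, not robustness to the full diversity of
real annotation pipelines.

## Numerical and scale choices

Alleles are capped at 10,000 bases per side (the registration cutoff,
checked at parse and register). Sequences are upper-cased on load; N is
allowed in references but any variant whose reference allele overlaps an N
fails validation, and N never appears in alternate alleles. The test
suite's problem sizes — 1000 random reconstruction round-trips, 10,000
shift-conservation cases, 300 exhaustive-enumeration comparisons on ≤50 bp
references, 1000 translation-oracle comparisons, a 10,000-record link
upload, the 1000-record dedup stream — were chosen so the whole suite
exercises every property at a scale where failures are not plausible
flukes while finishing in a few minutes on one CPU.

## Known limitations

Haplotypes are recognized and rejected as unsupported rather than modeled;
an indel that could be fractioned into independent simple variants is
treated as a single variant. Copy-number events without base-level
precision are out of scope. Insertions before the first base of a
reference cannot be written in HGVS and are refused by the formatter.
The store is single-process and in-memory with JSON persistence — an
embedded simplification of a transactional key-value engine, adequate for
desk-scale work and for the semantics (atomic batch registration, index
consistency) the tests pin down.
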