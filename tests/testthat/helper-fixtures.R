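# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: sequence diffing by full-string comparison,
# equivalent-representation search by exhaustive enumeration, translation by
# Biostrings on whole sequences.

# Table 1 / Table 2 toy references, built in code.
toy_db <- function() {
  refdb("TOY1", list(ref_record("TOY1", "genomic-primary", seq = "ACTGTCGTG")))
}

tri_db <- function() {
  refdb("R3", list(ref_record("R3", "genomic-primary",
                              seq = "AGTTCACTGCTGCTGCATCA")))
}

# Memoized seed-1 synthetic bundle + variant sets, generated once per run.
.fx_cache <- new.env(parent = emptyenv())
fx <- function() {
  if (is.null(.fx_cache$val)) {
    spec <- fixture_spec(seed = 1)
    dir <- file.path(tempdir(), "alleleReg-fixtures")
    bundle <- make_reference_bundle(spec, dir)
    sets <- make_variant_sets(spec, bundle)
    .fx_cache$val <- list(spec = spec, bundle = bundle, sets = sets,
                          db = bundle$db, manifest = bundle$manifest)
  }
  .fx_cache$val
}

# --- oracles -----------------------------------------------------------------

# Minimal-allele oracle: diff two full sequences by stripping the longest
# common prefix, then the longest common suffix of the remainders.
oracle_diff <- function(ref_id, ref_seq, alt_seq) {
  n1 <- nchar(ref_seq); n2 <- nchar(alt_seq)
  p <- 0L
  while (p < min(n1, n2) &&
         substr(ref_seq, p + 1, p + 1) == substr(alt_seq, p + 1, p + 1))
    p <- p + 1L
  s <- 0L
  while (s < min(n1, n2) - p &&
         substr(ref_seq, n1 - s, n1 - s) == substr(alt_seq, n2 - s, n2 - s))
    s <- s + 1L
  contextual_allele(ref_id, p, n1 - s,
                    substr(ref_seq, p + 1, n1 - s),
                    substr(alt_seq, p + 1, n2 - s))
}

# Exhaustive equivalent-representation oracle for short references: every
# same-category, same-length edit whose application reproduces the alternate
# sequence.
oracle_equivalents <- function(seq, allele) {
  target <- apply_allele(seq, allele)
  L <- nchar(seq)
  out <- list()
  if (nzchar(allele$ref) && !nzchar(allele$alt)) {
    w <- nchar(allele$ref)
    for (s in 0:(L - w)) {
      cand <- contextual_allele(allele$ref_id, s, s + w,
                                substr(seq, s + 1, s + w), "")
      if (apply_allele(seq, cand) == target) out[[length(out) + 1L]] <- cand
    }
  } else if (!nzchar(allele$ref) && nzchar(allele$alt)) {
    w <- nchar(allele$alt)
    for (s in 0:L) {
      # the inserted string is forced by the target sequence at that anchor
      ins <- substr(target, s + 1, s + w)
      cand <- contextual_allele(allele$ref_id, s, s, "", ins)
      if (apply_allele(seq, cand) == target) out[[length(out) + 1L]] <- cand
    }
  } else {
    out <- list(allele)
  }
  out
}

# Whole-protein translation oracle via Biostrings: translate the reference
# CDS and the alternate coding region (CDS start through transcript end),
# truncating at the first stop.
oracle_alt_protein <- function(db, allele) {
  rec <- alleleReg:::refdb_record(db, allele$ref_id)
  tx <- ref_sequence(db, allele$ref_id)
  alt_tx <- apply_allele(tx, trim_allele(allele))
  coding <- substr(alt_tx, rec$cds[1] + 1, nchar(alt_tx))
  coding <- substr(coding, 1, 3 * (nchar(coding) %/% 3))
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(coding),
                          if.fuzzy.codon = "X")))
  sub("\\*.*$", "", aa)
}

oracle_revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

expect_allele <- function(a, start, end, ref, alt) {
  expect_equal(a$start, start)
  expect_equal(a$end, end)
  expect_equal(a$ref, ref)
  expect_equal(a$alt, alt)
}
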