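# HGVS parsing, VCF intake and formatting.

test_that("the four printed variant categories parse to their attribute tuples", {
  db <- toy_db()
  expect_allele(parse_hgvs(db, "TOY1:g.5T>A"), 4, 5, "T", "A")
  expect_allele(parse_hgvs(db, "TOY1:g.4_5insAC"), 4, 4, "", "AC")
  expect_allele(parse_hgvs(db, "TOY1:g.4_7del"), 3, 7, "GTCG", "")
  expect_allele(parse_hgvs(db, "TOY1:g.3_6delinsCAA"), 2, 6, "TGTC", "CAA")
})

test_that("a stated reference allele that mismatches the sequence is rejected", {
  db <- toy_db()
  expect_error(parse_hgvs(db, "TOY1:g.5G>A"), class = "areg_reference_mismatch")
  expect_error(parse_hgvs(db, "TOY1:g.4_7delAAAA"),
               class = "areg_reference_mismatch")
  # bare del uses the positional span, no cross-check possible
  expect_allele(parse_hgvs(db, "TOY1:g.4_7delGTCG"), 3, 7, "GTCG", "")
})

test_that("VCF records trim to the oracle's minimal allele", {
  db <- toy_db()
  seq <- "ACTGTCGTG"
  cases <- list(list(4, "GT", "GA"), list(4, "G", "GAC"), list(3, "TGTCG", "T"))
  for (cs in cases) {
    got <- parse_vcf_record(db, "TOY1", cs[[1]], cs[[2]], cs[[3]])
    alt_full <- paste0(substr(seq, 1, cs[[1]] - 1), cs[[3]],
                       substr(seq, cs[[1]] + nchar(cs[[2]]), nchar(seq)))
    want <- oracle_diff("TOY1", seq, alt_full)
    expect_allele(got, want$start, want$end, want$ref, want$alt)
  }
  expect_allele(parse_vcf_record(db, "TOY1", 4, "GT", "GA"), 4, 5, "T", "A")
  expect_allele(parse_vcf_record(db, "TOY1", 4, "G", "GAC"), 4, 4, "", "AC")
  expect_allele(parse_vcf_record(db, "TOY1", 3, "TGTCG", "T"), 3, 7, "GTCG", "")
})

test_that("VCF records and the corresponding HGVS expressions agree", {
  expect_identical(unclass(parse_vcf_record(toy_db(), "TOY1", 4, "GT", "GA")),
                   unclass(parse_hgvs(toy_db(), "TOY1:g.5T>A")))
  expect_identical(unclass(parse_vcf_record(toy_db(), "TOY1", 4, "G", "GAC")),
                   unclass(parse_hgvs(toy_db(), "TOY1:g.4_5insAC")))
  expect_identical(unclass(parse_vcf_record(toy_db(), "TOY1", 3, "TGTCG", "T")),
                   unclass(parse_hgvs(toy_db(), "TOY1:g.4_7del")))
})

test_that("format then parse is the identity on random alleles of all categories", {
  db <- fx()$db
  g <- ref_sequence(db, "CHR1")
  set.seed(11)
  for (i in 1:1000) {
    p <- sample(3000, 1) + 100
    kind <- sample(c("snv", "ins", "del", "delins"), 1)
    a <- switch(kind,
      snv = {
        r <- substr(g, p + 1, p + 1)
        contextual_allele("CHR1", p, p + 1, r,
                          sample(setdiff(c("A", "C", "G", "T"), r), 1))
      },
      ins = contextual_allele("CHR1", p, p, "", random_seq(sample(1:5, 1))),
      del = {
        w <- sample(1:5, 1)
        contextual_allele("CHR1", p, p + w, substr(g, p + 1, p + w), "")
      },
      delins = {
        w <- sample(2:5, 1)
        ref <- substr(g, p + 1, p + w)
        alt <- random_seq(w + sample(-1:2, 1))
        if (alt == ref) next
        contextual_allele("CHR1", p, p + w, ref, alt)
      })
    a <- trim_allele(a)
    if (!nzchar(a$ref) && !nzchar(a$alt)) next
    back <- parse_hgvs(db, format_hgvs(db, a, "g"))
    expect_identical(unclass(back), unclass(trim_allele(a)))
  }
})

test_that("transcript numbering converts across UTR, CDS and intron positions", {
  db <- fx()$db
  cds <- fx()$manifest$coding_cds
  tx <- ref_sequence(db, "TXCOD1")
  at <- function(b) substr(tx, b + 1, b + 1)
  oth <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  # c.10 is transcript base cds_start + 9
  a <- parse_hgvs(db, sprintf("TXCOD1:c.10%s>%s", at(cds[1] + 9),
                              oth(at(cds[1] + 9))))
  expect_equal(a$start, cds[1] + 9)
  expect_identical(a$ref_id, "TXCOD1")
  # 5' UTR and 3' UTR anchors
  a5 <- parse_hgvs(db, sprintf("TXCOD1:c.-5%s>%s", at(cds[1] - 5),
                               oth(at(cds[1] - 5))))
  expect_equal(a5$start, cds[1] - 5)
  a3 <- parse_hgvs(db, sprintf("TXCOD1:c.*8%s>%s", at(cds[2] + 7),
                               oth(at(cds[2] + 7))))
  expect_equal(a3$start, cds[2] + 7)
  # intronic: expressed on the assembly, not the transcript
  g <- ref_sequence(db, "CHR1")
  gb <- substr(g, 701, 701)
  ai <- parse_hgvs(db, sprintf("TXCOD1:c.570+1%s>%s", gb, oth(gb)))
  expect_identical(ai$ref_id, "CHR1")
  expect_equal(ai$start, 700)
  # round-trip of the exonic transcript allele through c. formatting
  expect_identical(unclass(parse_hgvs(db, format_hgvs(db, a, "c"))),
                   unclass(a))
})

test_that("minus-strand intronic expressions strand-flip their alleles", {
  db <- fx()$db
  g <- ref_sequence(db, "CHR1")
  gb <- substr(g, 2500, 2500)             # genomic base for TXMIN1 c.280+1
  txb <- chartr("ACGT", "TGCA", gb)
  alt <- setdiff(c("A", "C", "G", "T"), txb)[1]
  ai <- parse_hgvs(db, sprintf("TXMIN1:c.280+1%s>%s", txb, alt))
  expect_identical(ai$ref_id, "CHR1")
  expect_equal(ai$start, 2499)
  expect_identical(ai$ref, gb)
  expect_identical(ai$alt, chartr("ACGT", "TGCA", alt))
})

test_that("duplications rewrite as 3'-edge insertions and inversions as delins", {
  db <- toy_db()
  # TOY1 = ACTGTCGTG; dup of bases 3-4 (TG) inserts TG after base 4
  d <- parse_hgvs(db, "TOY1:g.3_4dup")
  expect_allele(d, 4, 4, "", "TG")
  # stated duplicated sequence is cross-checked
  expect_error(parse_hgvs(db, "TOY1:g.3_4dupAA"),
               class = "areg_reference_mismatch")
  # inv of GTC is GAC; shared flanks trim away leaving the T>A core
  v <- parse_hgvs(db, "TOY1:g.4_6inv")
  expect_allele(v, 4, 5, "T", "A")
})

test_that("haplotype syntax and malformed input raise distinct errors", {
  db <- toy_db()
  expect_error(parse_hgvs(db, "TOY1:g.[4A>T;6del]"),
               class = "areg_not_supported")
  expect_error(parse_hgvs(db, "TOY1:g.banana"), class = "areg_syntax")
  expect_error(parse_hgvs(db, "NOPE:g.5T>A"), class = "areg_unknown_reference")
  expect_error(parse_hgvs(db, "TOY1:c.5T>A"),
               class = "areg_unsupported_numbering")
  expect_error(parse_hgvs(db, "TOY1:g.99T>A"), class = "areg_position")
})

test_that("c. formatting requires a CDS and g. formatting a genomic record", {
  db <- fx()$db
  a <- contextual_allele("TXE1", 14, 15,
                         substr(ref_sequence(db, "TXE1"), 15, 15), "")
  expect_error(format_hgvs(db, a, "c"), class = "areg_unsupported_numbering")
  expect_match(format_hgvs(db, a, "n"), "^TXE1:n\\.15del$")
  ag <- contextual_allele("CHR1", 10, 11,
                          substr(ref_sequence(db, "CHR1"), 11, 11), "")
  expect_error(format_hgvs(db, ag, "c"), class = "areg_unsupported_numbering")
})
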