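# Reference database: reconstruction from alignment encodings and
# bidirectional coordinate projection.

test_that("identity encoding reconstructs the target subsequence", {
  db <- refdb("G1", list(ref_record("G1", "genomic-primary",
                                    seq = "ACGTACGTACGTACGT")))
  refdb_add(db, ref_record("T1", "transcript",
                           alignment = alignment_encoding("G1", 4, 12, "8M")))
  expect_identical(reconstruct_sequence(db, "T1"),
                   substr("ACGTACGTACGTACGT", 5, 12))
})

test_that("insertions, substituted runs and tails splice into the rebuilt sequence", {
  g <- "ACGTACGTACGTACGT"
  db <- refdb("G1", list(ref_record("G1", "genomic-primary", seq = g)))
  # 3-base insertion after 4 aligned bases
  refdb_add(db, ref_record("TI", "transcript",
                           alignment = alignment_encoding(
                             "G1", 4, 12, "4M3I4M", c("", "TTT", ""))))
  manual <- paste0(substr(g, 5, 8), "TTT", substr(g, 9, 12))
  expect_identical(reconstruct_sequence(db, "TI"), manual)
  expect_equal(nchar(reconstruct_sequence(db, "TI")), 8 + 3)
  # substituted M run replaces the target bases wholesale
  refdb_add(db, ref_record("TS", "transcript",
                           alignment = alignment_encoding(
                             "G1", 0, 8, "4M4M", c("", "AAAA"))))
  expect_identical(reconstruct_sequence(db, "TS"),
                   paste0(substr(g, 1, 4), "AAAA"))
  # tails attach outside the aligned body
  refdb_add(db, ref_record("TT", "transcript",
                           alignment = alignment_encoding(
                             "G1", 4, 8, "4M", tail5 = "GG", tail3 = "C")))
  expect_identical(reconstruct_sequence(db, "TT"),
                   paste0("GG", substr(g, 5, 8), "C"))
})

test_that("minus-strand reconstruction equals the reverse-complement oracle", {
  g <- "ACGTTGCAACGGTTAA"
  db <- refdb("G1", list(ref_record("G1", "genomic-primary", seq = g)))
  refdb_add(db, ref_record("TM", "transcript", strand = "-",
                           alignment = alignment_encoding("G1", 2, 14,
                                                          "5M2D5M")))
  spliced <- paste0(substr(g, 3, 7), substr(g, 10, 14))
  expect_identical(reconstruct_sequence(db, "TM"), oracle_revcomp(spliced))
})

test_that("dangling alignment targets raise a missing-reference error", {
  db <- refdb("G1", list(ref_record("G1", "genomic-primary", seq = "ACGTACGT")))
  refdb_add(db, ref_record("TX", "transcript",
                           alignment = alignment_encoding("NOPE", 0, 4, "4M")))
  expect_error(reconstruct_sequence(db, "TX"), class = "areg_missing_reference")
})

test_that("alignment encodings validate their CIGAR length invariants", {
  expect_error(alignment_encoding("G1", 0, 10, "4M"), class = "areg_spec")
  expect_error(alignment_encoding("G1", 0, 4, "4M2I", c("", "T")),
               class = "areg_spec")
})

test_that("random spliced transcripts round-trip against a splicing oracle", {
  set.seed(101)
  for (i in 1:1000) {
    L <- sample(60:140, 1)
    g <- random_seq(L)
    db <- refdb("G", list(ref_record("G", "genomic-primary", seq = g)))
    n_ex <- sample(1:3, 1)
    cuts <- sort(sample(seq(2, L - 2), 2 * n_ex))
    starts <- cuts[seq(1, 2 * n_ex, 2)]; ends <- cuts[seq(2, 2 * n_ex, 2)]
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) next
    strand <- sample(c("+", "-"), 1)
    t5 <- if (i %% 5 == 0) random_seq(3) else ""
    ops <- character(0)
    for (k in seq_along(starts)) {
      if (k > 1) ops <- c(ops, paste0(starts[k] - ends[k - 1], "D"))
      ops <- c(ops, paste0(ends[k] - starts[k], "M"))
    }
    refdb_add(db, ref_record("T", "transcript", strand = strand,
                             alignment = alignment_encoding(
                               "G", starts[1], ends[length(ends)],
                               paste(ops, collapse = ""), tail5 = t5)))
    spliced <- paste(substring(g, starts + 1, ends), collapse = "")
    want <- paste0(t5, if (strand == "-") oracle_revcomp(spliced) else spliced)
    expect_identical(reconstruct_sequence(db, "T"), want)
  }
})

test_that("projection shifts coordinates across genomic deletions in the CIGAR", {
  g <- random_seq(40)
  db <- refdb("G", list(ref_record("G", "genomic-primary", seq = g)))
  refdb_add(db, ref_record("T", "transcript",
                           alignment = alignment_encoding("G", 5, 27,
                                                          "10M2D10M")))
  # per-base oracle: transcript base b maps to genome 5+b before the D and
  # 5+b+2 after it
  for (b in 0:19) {
    pr <- project_to_primary(db, "T", b, b + 1)
    expect_equal(pr$start, if (b < 10) 5 + b else 5 + b + 2)
  }
})

test_that("projection and back-projection are inverse on exonic intervals", {
  db <- fx()$db
  set.seed(7)
  for (tx in c("TXCOD1", "TXMIN1", "TXGR1")) {
    exons <- transcript_exons(db, tx)
    for (i in 1:50) {
      e <- exons[sample(nrow(exons), 1), ]
      s <- sample(seq(e[["start"]], e[["end"]] - 1), 1)
      w <- sample(1:min(5, e[["end"]] - s), 1)
      pr <- project_to_primary(db, tx, s, s + w)
      back <- project_from_primary(db, tx, pr$start, pr$end)
      expect_equal(back$start, s)
      expect_equal(back$end, s + w)
    }
  }
})

test_that("insertion anchors at junctions land on the upstream exon's 3' end", {
  db <- fx()$db
  # plus strand: TXCOD1 exon1 ends at transcript 600 <-> genomic 700
  pj <- project_to_primary(db, "TXCOD1", 600, 600)
  expect_equal(pj$start, 700)
  expect_equal(pj$end, 700)
  # minus strand: TXMIN1 exon1 (transcript 5') ends at tx 300 <-> genomic 2500
  pjm <- project_to_primary(db, "TXMIN1", 300, 300)
  expect_equal(pjm$start, 2500)
})

test_that("tails are unalignable and edit-spanning intervals are unprojectable", {
  db <- fx()$db
  expect_error(project_to_primary(db, "TXTAIL1", 2, 3),
               class = "areg_unalignable")
  expect_error(project_to_primary(db, "TXCOD1", 595, 605),
               class = "areg_unprojectable")
})

test_that("transcript positions with intron offsets resolve strand-aware", {
  db <- fx()$db
  # exonic anchor: 10th coding base of TXCOD1 (cds starts at 30)
  r <- resolve_transcript_position(db, "TXCOD1", "10", "c")
  expect_equal(r$base, 100 + 30 + 9)   # exon1 starts at genomic 100
  # donor +1 and acceptor -1 around intron 1 (genomic [700, 800))
  expect_equal(resolve_transcript_position(db, "TXCOD1", "570+1", "c")$base, 700)
  expect_equal(resolve_transcript_position(db, "TXCOD1", "571-1", "c")$base, 799)
  # minus strand: +1 from the donor steps numerically below the exon start
  expect_equal(resolve_transcript_position(db, "TXMIN1", "280+1", "c")$base, 2499)
  expect_equal(resolve_transcript_position(db, "TXMIN1", "281-1", "c")$base, 2400)
  # offsets that do not land in an intron are invalid
  expect_error(resolve_transcript_position(db, "TXCOD1", "10+5", "c"),
               class = "areg_invalid_position")
  expect_error(resolve_transcript_position(db, "TXCOD1", "570+200", "c"),
               class = "areg_invalid_position")
})
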