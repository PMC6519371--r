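# Canonicalization keys, CAid registration, queries, merge/split,
# persistence.

test_that("transcripts sharing an exon canonicalize a shared substitution identically", {
  db <- fx()$db
  # the shared exon covers genomic [800, 1500): pick a base and express the
  # substitution on TXCOD1 (c.), TXE1 (n.) and the assembly (g.)
  g <- ref_sequence(db, "CHR1")
  gpos <- 900
  gb <- substr(g, gpos + 1, gpos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), gb)[1]
  on_cod <- project_from_primary(db, "TXCOD1", gpos, gpos + 1)
  on_e1 <- project_from_primary(db, "TXE1", gpos, gpos + 1)
  a_cod <- contextual_allele("TXCOD1", on_cod$start, on_cod$end, gb, alt)
  a_e1 <- contextual_allele("TXE1", on_e1$start, on_e1$end, gb, alt)
  a_g <- contextual_allele("CHR1", gpos, gpos + 1, gb, alt)
  keys <- vapply(list(a_cod, a_e1, a_g),
                 function(a) canonicalize(db, a)$key, "")
  # oracle: rebuild the genomic alternate sequence through each transcript
  expect_length(unique(keys), 1)
})

test_that("the acceptor G-run spellings c.N-1delG and c.NdelG share one CAid", {
  f <- fx()
  reg <- allele_registry(f$db)
  ca1 <- register_allele(reg, sprintf("TXGR1:c.%ddelG", f$manifest$grun_c))
  ca2 <- register_allele(reg, sprintf("TXGR1:c.%d-1delG", f$manifest$grun_c))
  expect_identical(ca1, ca2)
  # and the key is the left-aligned genomic deletion at the run start
  r <- query_caid(reg, ca1)
  expect_equal(r$key_allele$start, f$manifest$grun_genomic_run[1])
})

test_that("a genomic SNV and its minus-strand transcript spelling share one key", {
  db <- fx()$db
  g <- ref_sequence(db, "CHR1")
  a_tx <- parse_hgvs(db, "TXMIN1:c.30T>A")
  pr <- project_to_primary(db, "TXMIN1", 49, 50)
  a_g <- contextual_allele("CHR1", pr$start, pr$end,
                           substr(g, pr$start + 1, pr$end),
                           oracle_revcomp("A"))
  expect_identical(canonicalize(db, a_tx)$key, canonicalize(db, a_g)$key)
})

test_that("canonicalization is invariant across equivalent representations", {
  db <- fx()$db
  g <- ref_sequence(db, "CHR1")
  set.seed(47)
  for (i in 1:200) {
    p <- sample(7000, 1) + 50
    a <- if (i %% 2 == 0) {
      w <- sample(1:3, 1)
      contextual_allele("CHR1", p, p + w, substr(g, p + 1, p + w), "")
    } else contextual_allele("CHR1", p, p, "", random_seq(sample(1:3, 1)))
    keys <- vapply(enumerate_equivalents(db, a),
                   function(m) canonicalize(db, m)$key, "")
    expect_length(unique(keys), 1)
  }
})

test_that("registration is idempotent and counters issue sequential CAids", {
  f <- fx()
  reg <- allele_registry(f$db)
  ca <- register_allele(reg, "TXCOD1:c.736A>C")
  expect_identical(register_allele(reg, "TXCOD1:c.736A>C"), ca)
  # left- and right-aligned spellings of the repeat deletion register once
  db2 <- tri_db()
  reg2 <- allele_registry(db2)
  c_l <- register_allele(reg2, contextual_allele("R3", 6, 9, "CTG", ""))
  c_r <- register_allele(reg2, contextual_allele("R3", 13, 16, "TGC", ""))
  expect_identical(c_l, c_r)
  # bulk: n distinct SNVs get n sequential identifiers
  g <- ref_sequence(f$db, "CHR1")
  reg3 <- allele_registry(f$db)
  ids <- vapply(0:24, function(k) {
    p <- 6000 + 3 * k
    b <- substr(g, p + 1, p + 1)
    register_allele(reg3, contextual_allele("CHR1", p, p + 1, b,
                                            setdiff(c("A", "C", "G", "T"), b)[1]))
  }, "")
  expect_identical(ids, paste0("CA", 1:25))
})

test_that("registration enforces the 10 kb allele size cutoff", {
  db <- refdb("B1", list(ref_record("B1", "genomic-primary",
                                    seq = "TTTTCCCCGGGG")))
  reg <- allele_registry(db)
  ok <- register_allele(reg, contextual_allele("B1", 4, 4, "",
                                               strrep("AC", 5000)))
  expect_match(ok, "^CA[0-9]+$")
  expect_error(register_allele(reg, contextual_allele("B1", 4, 4, "",
                                                      paste0(strrep("AC", 5000), "G"))),
               class = "areg_size_limit")
})

test_that("queries resolve by CAid, HGVS, external id, region and gene+partial", {
  f <- fx()
  reg <- allele_registry(f$db)
  ca <- register_allele(reg, "TXCOD1:c.736A>C", external = c("clinvar", "V001"))
  expect_identical(query_caid(reg, ca)$caid, ca)
  expect_identical(query_hgvs(reg, "TXCOD1:c.736A>C")$caid, ca)
  expect_identical(query_external(reg, "clinvar", "V001")$caid, ca)
  expect_error(query_caid(reg, "banana"), class = "areg_query_syntax")
  expect_null(query_external(reg, "clinvar", "V999"))
  # region: the canonical key of c.736A>C lies at genomic 965
  hits <- query_region(reg, 900, 1000)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$caid, ca)
  expect_length(query_region(reg, 0, 100), 0)
  # gene+partial: c.5 is A on two of the three GENED transcripts
  tab <- query_gene_partial(reg, "GENED", "c.5A>T")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$valid), 2)
  expect_equal(sum(!tab$valid), 1)
  expect_match(tab$error[!tab$valid], "mismatch")
})

test_that("merging deactivates the loser but keeps it dereferenceable", {
  f <- fx()
  reg <- allele_registry(f$db)
  w <- register_allele(reg, "TXCOD1:c.736A>C")
  l <- register_allele(reg, "TXCOD1:c.10T>A")
  n_members <- length(query_caid(reg, w)$members) +
    length(query_caid(reg, l)$members)
  merge_caids(reg, w, l)
  lr <- query_caid(reg, l)
  expect_identical(lr$status, "inactive")
  expect_identical(lr$replaced_by, w)
  expect_length(lr$members, 1)        # loser retains its members
  expect_length(query_caid(reg, w)$members, n_members)
  # re-registering a loser member resolves to the winner
  expect_identical(register_allele(reg, "TXCOD1:c.10T>A"), w)
  expect_identical(query_hgvs(reg, "TXCOD1:c.10T>A")$caid, w)
  # merging an inactive record is a state error
  expect_error(merge_caids(reg, w, l), class = "areg_state")
})

test_that("every CAid ever issued stays resolvable across merges and splits", {
  f <- fx()
  reg <- allele_registry(f$db)
  g <- ref_sequence(f$db, "CHR1")
  mk <- function(p) {
    b <- substr(g, p + 1, p + 1)
    contextual_allele("CHR1", p, p + 1, b, setdiff(c("A", "C", "G", "T"), b)[1])
  }
  ids <- vapply(seq(6000, 6040, 4), function(p) register_allele(reg, mk(p)), "")
  merge_caids(reg, ids[1], ids[2])
  merge_caids(reg, ids[1], ids[3])
  succ <- split_caid(reg, ids[4], list(list(mk(6100)), list(mk(6104))))
  for (id in c(ids, succ)) expect_false(is.null(query_caid(reg, id)))
  # counter never reuses identifiers
  all_ids <- names(reg$records)
  expect_identical(anyDuplicated(all_ids), 0L)
  new_id <- register_allele(reg, mk(6200))
  expect_false(new_id %in% ids)
})

test_that("serialize and reload reproduce the store byte-identically", {
  f <- fx()
  reg <- allele_registry(f$db)
  register_allele(reg, "TXCOD1:c.736A>C", external = c("clinvar", "V001"))
  register_allele(reg, "TXMIN1:c.30T>A")
  register_allele(reg, sprintf("TXGR1:c.%ddelG", f$manifest$grun_c))
  merge_caids(reg, "CA1", "CA2")
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  registry_save(reg, p1)
  reg2 <- registry_load(p1, f$db)
  registry_save(reg2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(query_hgvs(reg2, "TXCOD1:c.736A>C")$caid, "CA1")
})

test_that("alleles on unaligned references register under reference-local keys", {
  f <- fx()
  reg <- allele_registry(f$db)
  seq <- ref_sequence(f$db, "REFLOC1")
  b <- substr(seq, 11, 11)
  a <- contextual_allele("REFLOC1", 10, 11, b,
                         setdiff(c("A", "C", "G", "T"), b)[1])
  ca <- register_allele(reg, a)
  r <- query_caid(reg, ca)
  expect_false(r$canonicalizable)
  expect_match(r$key, "^local\\|")
})
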