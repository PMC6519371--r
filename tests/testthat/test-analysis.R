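# Deduplication and discordance mining.

test_that("a literally repeated record counts as one duplicate", {
  db <- toy_db()
  rep1 <- find_duplicates(db, c("TOY1:g.5T>A", "TOY1:g.5T>A"))
  expect_equal(rep1$n_duplicates, 1)
  expect_length(rep1$groups, 1)
})

test_that("left- and right-aligned spellings of a repeat deletion are duplicates", {
  db <- tri_db()
  rep1 <- find_duplicates(db, list(contextual_allele("R3", 6, 9, "CTG", ""),
                                   contextual_allele("R3", 13, 16, "TGC", "")))
  expect_equal(rep1$n_processed, 2)
  expect_equal(rep1$n_duplicates, 1)
})

test_that("the fixture stream recovers exactly the planted duplicate count", {
  f <- fx()
  rep1 <- find_duplicates(f$db, f$sets$vcf)
  expect_equal(rep1$n_input, f$sets$truth$n_vcf_records)
  expect_equal(rep1$n_skipped, f$sets$truth$n_invalid)
  expect_equal(rep1$n_processed, f$sets$truth$n_valid)
  expect_equal(rep1$n_duplicates, f$sets$truth$planted_duplicates)
  # the duplicate groups are exactly the planted twin pairs
  got_pairs <- unname(lapply(rep1$groups, sort))
  want_pairs <- lapply(f$sets$truth$duplicate_pairs, sort)
  expect_setequal(lapply(got_pairs, paste, collapse = ","),
                  lapply(want_pairs, paste, collapse = ","))
})

test_that("deduplication counts are invariant under input permutation", {
  f <- fx()
  parsed <- read_vcf_alleles(f$db, f$sets$vcf)
  alleles <- parsed$alleles[!vapply(parsed$alleles, is.null, NA)]
  alleles <- alleles[1:200]
  r1 <- find_duplicates(f$db, alleles)
  set.seed(3)
  r2 <- find_duplicates(f$db, alleles[sample(length(alleles))])
  expect_equal(r1$n_duplicates, r2$n_duplicates)
  expect_equal(r1$n_distinct, r2$n_distinct)
  expect_identical(names(r1$groups), names(r2$groups))
})

test_that("concordant same-effect pairs increment the diagonal", {
  f <- fx()
  at <- data.frame(hgvs = f$sets$truth$met_pair_hgvs,
                   classification = c("pathogenic", "likely-pathogenic"),
                   stringsAsFactors = FALSE)
  dm <- discordance_matrix(f$db, at)
  expect_equal(dm$matrix["pathogenic", "pathogenic"], 1)
  expect_equal(sum(dm$matrix), 1)
  expect_equal(nrow(dm$discordant), 0)
})

test_that("an engineered assertion set reproduces its planted cell pattern", {
  f <- fx()
  met <- f$manifest$met_codons
  pair <- function(codon) sprintf("TXCOD1:c.%dA>%s", 3 * (codon - 1) + 1,
                                  c("C", "T"))
  rows <- list()
  for (k in 1:3)
    rows[[length(rows) + 1]] <- data.frame(hgvs = pair(met[k]),
                                           classification = c("benign", "uncertain"))
  for (k in 4:5)
    rows[[length(rows) + 1]] <- data.frame(hgvs = pair(met[k]),
                                           classification = c("uncertain", "pathogenic"))
  at <- do.call(rbind, rows)
  dm <- discordance_matrix(f$db, at)
  want <- matrix(0L, 3, 3, dimnames = dimnames(dm$matrix))
  want["uncertain", "benign"] <- 3L
  want["pathogenic", "uncertain"] <- 2L
  expect_identical(dm$matrix, want)
  expect_equal(nrow(dm$discordant), 5)
})

test_that("the codon-246 pair with split assertions appears in the discordant list", {
  f <- fx()
  at <- read.table(f$sets$assertions, sep = "\t", header = TRUE,
                   colClasses = "character")
  dm <- discordance_matrix(f$db, at)
  hit <- dm$discordant$hgvs_a %in% f$sets$truth$met_pair_hgvs &
    dm$discordant$hgvs_b %in% f$sets$truth$met_pair_hgvs
  expect_equal(sum(hit), 1)
  expect_setequal(unlist(dm$discordant[hit, c("class_a", "class_b")]),
                  c("uncertain", "pathogenic"))
})

test_that("matrix cells sum to the number of qualifying pairs", {
  f <- fx()
  at <- read.table(f$sets$assertions, sep = "\t", header = TRUE,
                   colClasses = "character")
  dm <- discordance_matrix(f$db, at)
  expect_equal(sum(dm$matrix), nrow(dm$pairs))
  expect_equal(sum(dm$matrix), f$sets$truth$n_assertion_pairs)
  expect_identical(dm$matrix, f$sets$truth$assertion_matrix)
})

test_that("conflicting assertions on one variant keep the most severe", {
  f <- fx()
  met <- f$manifest$met_codons
  v <- sprintf("TXCOD1:c.%dA>%s", 3 * (met[1] - 1) + 1, c("C", "T"))
  at <- data.frame(hgvs = c(v[1], v[1], v[2]),
                   classification = c("benign", "pathogenic", "uncertain"),
                   stringsAsFactors = FALSE)
  dm <- discordance_matrix(f$db, at)
  expect_equal(dm$matrix["pathogenic", "uncertain"], 1)
  expect_equal(sum(dm$matrix), 1)
})

test_that("unresolvable assertion rows are excluded with a reason", {
  f <- fx()
  at <- data.frame(hgvs = c(f$sets$truth$met_pair_hgvs, "TXCOD1:c.736G>A"),
                   classification = c("benign", "benign", "benign"),
                   stringsAsFactors = FALSE)
  dm <- discordance_matrix(f$db, at)
  expect_equal(nrow(dm$excluded), 1)
  expect_match(dm$excluded$reason, "mismatch")
  expect_error(discordance_matrix(f$db, data.frame(
    hgvs = "x", classification = "odd")), class = "areg_query_syntax")
})

test_that("frequency discordance applies the rare/common thresholds", {
  f <- fx()
  met <- f$manifest$met_codons
  pair <- function(codon) sprintf("TXCOD1:c.%dA>%s", 3 * (codon - 1) + 1,
                                  c("C", "T"))
  ft <- rbind(data.frame(hgvs = pair(met[1]), af = c(0.005, 0.06)),
              data.frame(hgvs = pair(met[2]), af = c(0.02, 0.04)))
  fr <- frequency_discordance(f$db, ft)
  expect_equal(fr$n_groups_tested, 2)
  expect_length(fr$groups, 1)
  expect_equal(fr$groups[[1]]$min_af, 0.005)
  expect_equal(fr$groups[[1]]$max_af, 0.06)
  expect_error(frequency_discordance(f$db, data.frame(hgvs = "x", af = 1.2)),
               class = "areg_query_syntax")
})

test_that("the fixture frequency table recovers the planted discordant groups", {
  f <- fx()
  ft <- read.table(f$sets$frequencies, sep = "\t", header = TRUE)
  fr <- frequency_discordance(f$db, ft)
  expect_equal(fr$n_groups_tested, f$sets$truth$n_frequency_groups)
  expect_length(fr$groups, f$sets$truth$planted_discordant_groups)
})

test_that("mining is pure: repeated runs produce identical reports", {
  f <- fx()
  at <- read.table(f$sets$assertions, sep = "\t", header = TRUE,
                   colClasses = "character")
  expect_identical(discordance_matrix(f$db, at), discordance_matrix(f$db, at))
  r1 <- find_duplicates(f$db, f$sets$vcf)
  r2 <- find_duplicates(f$db, f$sets$vcf)
  expect_identical(r1, r2)
})
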