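# Deterministic synthetic fixtures: a toy assembly with multi-exon
# transcripts on both strands, a coding transcript with planted ATG codons
# (codon 246 among them), a transcript whose acceptor site sits inside a
# G run, homopolymer/trinucleotide repeat tracts for shiftable indels, and
# variant/assertion/frequency sets with planted structure recorded in a
# truth table. Same seed, byte-identical outputs.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Codons that are neither ATG nor a stop, used as neutral CDS filler.
SAFE_CODONS <- c("GCT", "GCA", "CCT", "GGT", "TTC", "ATC", "GTC", "CAA",
                 "GAA", "TGC", "ACT", "AGC")

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specify a synthetic fixture set
#'
#' The defaults are the bundled study conditions: an 8 kb toy assembly, a
#' 1000-record variant stream with 50 planted shifted-twin duplicate pairs
#' and 3 invalid records, 100 same-protein-effect frequency groups of which
#' 4 are planted discordant, and an assertion table with 3 benign-uncertain
#' and 2 uncertain-pathogenic planted discordant pairs plus the codon-246
#' Met-to-Leu pair.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param genome_length Toy assembly length (bases).
#' @param repeat_tracts List of `list(motif, copies)` tracts planted in
#'   intergenic sequence for shiftable indels.
#' @param n_variants Records in the generated VCF (valid ones).
#' @param planted_duplicates Number of shifted-twin pairs among them.
#' @param n_invalid Invalid records appended (reference-mismatch).
#' @param n_frequency_groups Same-protein-effect groups in the frequency
#'   table.
#' @param planted_discordant_groups How many of those cross both frequency
#'   thresholds.
#' @param assertion_pairs Named integer vector: planted pair counts for
#'   cells `benign_uncertain`, `uncertain_pathogenic`, `benign_benign`,
#'   `uncertain_uncertain`, `pathogenic_pathogenic`.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         genome_length = 8000L,
                         repeat_tracts = list(list(motif = "CTG", copies = 4L),
                                              list(motif = "A", copies = 6L)),
                         n_variants = 1000L,
                         planted_duplicates = 50L,
                         n_invalid = 3L,
                         n_frequency_groups = 100L,
                         planted_discordant_groups = 4L,
                         assertion_pairs = c(benign_uncertain = 3L,
                                             uncertain_pathogenic = 2L,
                                             benign_benign = 2L,
                                             uncertain_uncertain = 2L,
                                             pathogenic_pathogenic = 1L)) {
  if (genome_length < 6000L)
    areg_abort("areg_spec", "the toy assembly needs at least 6000 bases")
  if (2L * planted_duplicates > n_variants)
    areg_abort("areg_spec", "more planted duplicate records than variants")
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 repeat_tracts = repeat_tracts,
                 n_variants = as.integer(n_variants),
                 planted_duplicates = as.integer(planted_duplicates),
                 n_invalid = as.integer(n_invalid),
                 n_frequency_groups = as.integer(n_frequency_groups),
                 planted_discordant_groups = as.integer(planted_discordant_groups),
                 assertion_pairs = assertion_pairs),
            class = "fixture_spec")
}

# transcript-base -> genomic-base map for an exon layout (genome order)
tx2g_map <- function(exon_starts, exon_ends, strand) {
  g <- unlist(Map(function(s, e) seq.int(s, e - 1L), exon_starts, exon_ends))
  if (strand == "-") rev(g) else g
}

plant_tx <- function(chars, map, tx_from, content, strand) {
  cs <- strsplit(content, "")[[1]]
  for (k in seq_along(cs)) {
    g <- map[tx_from + k]         # map is 1-based over transcript bases
    chars[g + 1L] <- if (strand == "-") COMP[[cs[k]]] else cs[k]
  }
  chars
}

build_cds_content <- function(n_codons, atg_codons) {
  fill <- SAFE_CODONS[(seq_len(n_codons) %% length(SAFE_CODONS)) + 1L]
  fill[1L] <- "ATG"
  fill[n_codons] <- "TAA"
  fill[atg_codons] <- "ATG"
  paste(fill, collapse = "")
}

#' Generate the toy reference bundle
#'
#' Writes a FASTA (toy assembly `CHR1` plus an unaligned verbatim reference
#' `REFLOC1`), an alignment table and a JSON config to `dir`, plus a
#' `manifest.json` recording every planted feature. The bundle contains a
#' plus-strand 3-exon coding transcript (`TXCOD1`, ATG at codon 246 and at
#' a run of reserved codons), a minus-strand coding transcript (`TXMIN1`),
#' a transcript with a G run spanning its acceptor site (`TXGR1`), three
#' same-gene transcripts differing at c.5 (`TXD1..3`), a non-coding
#' transcript sharing exons with `TXCOD1` (`TXE1`), a tailed transcript
#' (`TXTAIL1`), and the repeat tracts from the spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List: `db` (the loaded `allele_refdb`), `config` (path),
#'   `manifest` (planted-feature list), `dir`.
#' @export
make_reference_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    L <- spec$genome_length
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

    # --- TXCOD1: plus strand, 3 exons, 420-codon CDS --------------------
    cod_exons_g <- list(s = c(100L, 800L, 1560L), e = c(700L, 1500L, 1710L))
    cod_map <- tx2g_map(cod_exons_g$s, cod_exons_g$e, "+")
    cod_cds <- c(30L, 30L + 1260L)
    n_codons <- 420L
    n_pairs_needed <- sum(spec$assertion_pairs) + spec$n_frequency_groups
    candidates <- setdiff(seq(8L, n_codons - 3L), 246L)
    if (n_pairs_needed > length(candidates))
      areg_abort("areg_spec", "too many planted pairs for the CDS size")
    met_codons <- candidates[seq_len(n_pairs_needed)]
    chars <- plant_tx(chars, cod_map, cod_cds[1],
                      build_cds_content(n_codons, c(246L, met_codons)), "+")

    # --- TXMIN1: minus strand, 2 exons, 200-codon CDS -------------------
    min_exons_g <- list(s = c(2000L, 2500L), e = c(2400L, 2800L))
    min_map <- tx2g_map(min_exons_g$s, min_exons_g$e, "-")
    min_cds <- c(20L, 20L + 600L)
    chars <- plant_tx(chars, min_map, min_cds[1],
                      build_cds_content(200L, integer(0)), "-")

    # --- TXGR1: G run across the acceptor of intron 1 -------------------
    gr_exons_g <- list(s = c(3000L, 3390L), e = c(3300L, 3690L))
    # four G's across the acceptor: last two intron bases (0-based 3388-3389)
    # and first two exon-2 bases (3390-3391), bounded by non-G on both sides
    chars[3388] <- "T"
    chars[3389:3392] <- "G"
    chars[3393] <- "C"
    gr_cds <- c(12L, 12L + 510L)
    grun_c <- 300L - gr_cds[1] + 1L     # c-number of the first base of exon 2

    # --- TXD1..3: same gene, offset starts, c.5 = A,A,C -----------------
    d_starts <- c(4000L, 4001L, 4002L)
    chars[4014 + 1L] <- "A"; chars[4015 + 1L] <- "A"; chars[4016 + 1L] <- "C"

    # --- repeat tracts in intergenic sequence ---------------------------
    tract_pos <- 5000L
    tracts <- list()
    for (tr in spec$repeat_tracts) {
      tract <- strrep(tr$motif, tr$copies)
      w <- nchar(tract)
      # break the repeat on both flanks
      flank <- setdiff(c("A", "C", "G", "T"),
                       c(substr(tract, 1L, 1L), substr(tract, w, w)))
      chars[tract_pos] <- flank[1]
      chars[tract_pos + seq_len(w)] <- strsplit(tract, "")[[1]]
      chars[tract_pos + w + 1L] <- flank[2]
      tracts[[length(tracts) + 1L]] <-
        list(motif = tr$motif, copies = tr$copies, start = tract_pos)
      tract_pos <- tract_pos + w + 20L
    }

    genome <- paste(chars, collapse = "")
    refloc <- paste(sample(c("A", "C", "G", "T"), 200L, replace = TRUE),
                    collapse = "")

    mkaln <- function(starts, ends) {
      ops <- character(0)
      for (i in seq_along(starts)) {
        if (i > 1L) ops <- c(ops, paste0(starts[i] - ends[i - 1L], "D"))
        ops <- c(ops, paste0(ends[i] - starts[i], "M"))
      }
      alignment_encoding("CHR1", starts[1], ends[length(ends)],
                         paste(ops, collapse = ""))
    }
    tx_exons <- function(starts, ends, strand, n5 = 0L) {
      lens <- ends - starts
      if (strand == "-") lens <- rev(lens)
      e <- cumsum(lens) + n5
      cbind(start = c(n5, e[-length(e)]), end = e)
    }
    recs <- list(
      ref_record("TXCOD1", "transcript", alignment = mkaln(cod_exons_g$s, cod_exons_g$e),
                 strand = "+", cds = cod_cds,
                 exons = tx_exons(cod_exons_g$s, cod_exons_g$e, "+"),
                 gene = "GENEA"),
      ref_record("TXE1", "transcript",
                 alignment = mkaln(c(800L, 1560L), c(1500L, 1710L)),
                 strand = "+",
                 exons = tx_exons(c(800L, 1560L), c(1500L, 1710L), "+"),
                 gene = "GENEA"),
      ref_record("TXMIN1", "transcript", alignment = mkaln(min_exons_g$s, min_exons_g$e),
                 strand = "-", cds = min_cds,
                 exons = tx_exons(min_exons_g$s, min_exons_g$e, "-"),
                 gene = "GENEB"),
      ref_record("TXGR1", "transcript", alignment = mkaln(gr_exons_g$s, gr_exons_g$e),
                 strand = "+", cds = gr_cds,
                 exons = tx_exons(gr_exons_g$s, gr_exons_g$e, "+"),
                 gene = "GENEC"),
      ref_record("TXTAIL1", "transcript",
                 alignment = alignment_encoding("CHR1", 4300L, 4500L, "200M",
                                                tail5 = "ACGTT"),
                 strand = "+", gene = "GENEE")
    )
    for (i in 1:3)
      recs[[length(recs) + 1L]] <-
        ref_record(paste0("TXD", i), "transcript",
                   alignment = mkaln(d_starts[i], d_starts[i] + 90L),
                   strand = "+", cds = c(10L, 70L),
                   exons = cbind(start = 0L, end = 90L), gene = "GENED")

    fa <- file.path(dir, "genome.fa")
    ss <- Biostrings::DNAStringSet(c(CHR1 = genome, REFLOC1 = refloc))
    Biostrings::writeXStringSet(ss, fa, width = 70L)
    aln_path <- file.path(dir, "alignments.tsv")
    write_alignment_table(recs, aln_path)
    config <- file.path(dir, "config.json")
    jsonlite::write_json(list(primary = "CHR1", fasta = "genome.fa",
                              alignments = "alignments.tsv"),
                         config, auto_unbox = TRUE, pretty = TRUE)
    manifest <- list(
      seed = spec$seed, genome_length = spec$genome_length,
      coding_tx = "TXCOD1", coding_cds = cod_cds, n_codons = n_codons,
      met_codons = met_codons,
      minus_tx = "TXMIN1", minus_cds = min_cds,
      grun_tx = "TXGR1", grun_c = grun_c,
      grun_genomic_run = c(3388L, 3392L),  # interbase: 4 G's at [3388,3392)
      gened_tx = paste0("TXD", 1:3), gened_c5 = c("A", "A", "C"),
      shared_exon_tx = c("TXCOD1", "TXE1"),
      shared_exon_genomic = c(800L, 1500L),
      tailed_tx = "TXTAIL1", local_ref = "REFLOC1",
      repeat_tracts = tracts,
      donor_c = 570L, acceptor_c = 571L   # TXCOD1 exon1/exon2 boundary
    )
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(db = load_reference_bundle(config), config = config,
         manifest = manifest, dir = dir)
  })
}

# left/right-aligned VCF spellings of a single-base deletion at run start
vcf_spellings <- function(db, seq, a) {
  nz <- normalize_allele(db, a)
  sp <- function(k) {
    anchor <- substr(seq, k$start, k$start)
    list(pos = k$start, ref = paste0(anchor, k$ref), alt = anchor)
  }
  list(left = sp(nz$left_aligned), right = sp(nz$right_aligned),
       key = canonicalize(db, a)$key,
       shiftable = nz$left_aligned$start != nz$right_aligned$start)
}

#' Generate variant, assertion and frequency sets over a reference bundle
#'
#' Writes `variants.vcf` (background SNVs plus planted left-/right-aligned
#' spellings of the same deletions, plus invalid records), `hgvs.txt` (a
#' parseable expression list across g./c./n. flavors), `assertions.tsv` and
#' `frequencies.tsv` (Met-to-Leu pairs at reserved codons of the coding
#' transcript), and `truth.json` with the planted bookkeeping.
#'
#' @param spec A [fixture_spec()].
#' @param bundle Result of [make_reference_bundle()].
#' @param dir Output directory (defaults to the bundle directory).
#' @return List of paths plus the `truth` list.
#' @export
make_variant_sets <- function(spec, bundle, dir = bundle$dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- bundle$db
  man <- bundle$manifest
  with_seed(spec$seed + 1L, {
    genome <- ref_sequence(db, "CHR1")
    L <- nchar(genome)
    keys <- new.env(parent = emptyenv())
    seen <- function(k) exists(k, envir = keys)
    note <- function(k) assign(k, TRUE, envir = keys)

    # --- planted duplicate pairs: 1-base deletions in homopolymer runs ---
    rl <- rle(strsplit(genome, "")[[1]])
    run_start <- cumsum(c(0L, rl$lengths))[seq_along(rl$lengths)]
    runs <- data.frame(start = run_start, len = rl$lengths)
    runs <- runs[runs$len >= 2L & runs$start >= 5200L &
                   runs$start + runs$len < L - 2L, ]
    if (nrow(runs) < spec$planted_duplicates)
      areg_abort("areg_spec", "not enough homopolymer runs for planted duplicates")
    runs <- runs[seq_len(spec$planted_duplicates), ]
    vcf_rows <- list()
    dup_pairs <- list()
    for (i in seq_len(nrow(runs))) {
      a <- contextual_allele("CHR1", runs$start[i], runs$start[i] + 1L,
                             substr(genome, runs$start[i] + 1L, runs$start[i] + 1L), "")
      sp <- vcf_spellings(db, genome, a)
      note(sp$key)
      i1 <- length(vcf_rows) + 1L
      vcf_rows[[i1]] <- list(chrom = "CHR1", pos = sp$left$pos,
                             ref = sp$left$ref, alt = sp$left$alt)
      vcf_rows[[i1 + 1L]] <- list(chrom = "CHR1", pos = sp$right$pos,
                                  ref = sp$right$ref, alt = sp$right$alt)
      dup_pairs[[i]] <- c(i1, i1 + 1L)
    }

    # --- background SNVs with pairwise-distinct canonical keys ----------
    n_bg <- spec$n_variants - 2L * spec$planted_duplicates
    made <- 0L
    while (made < n_bg) {
      p <- sample.int(L - 2L, 1L)        # 0-based position in [1, L-2]
      refb <- substr(genome, p + 1L, p + 1L)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      k <- paste("CHR1", p, p + 1L, altb, sep = "|")
      if (seen(k)) next
      note(k)
      vcf_rows[[length(vcf_rows) + 1L]] <- list(chrom = "CHR1", pos = p + 1L,
                                                ref = refb, alt = altb)
      made <- made + 1L
    }
    # --- invalid records: stated REF disagrees with the assembly --------
    inv_idx <- integer(0)
    for (i in seq_len(spec$n_invalid)) {
      p <- sample.int(L - 2L, 1L)
      refb <- substr(genome, p + 1L, p + 1L)
      wrong <- setdiff(c("A", "C", "G", "T"), refb)[1]
      vcf_rows[[length(vcf_rows) + 1L]] <- list(chrom = "CHR1", pos = p + 1L,
                                                ref = wrong, alt = refb)
      inv_idx <- c(inv_idx, length(vcf_rows))
    }
    ord <- sample.int(length(vcf_rows))   # shuffle; dedup is order-invariant
    vcf_rows <- vcf_rows[ord]
    remap <- match(seq_along(ord), ord)
    dup_pairs <- lapply(dup_pairs, function(p) sort(remap[p]))
    inv_idx <- sort(remap[inv_idx])

    vcf_path <- file.path(dir, "variants.vcf")
    vcf_lines <- c("##fileformat=VCFv4.2",
                   paste0("##contig=<ID=CHR1,length=", L, ">"),
                   paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", sep = "\t"),
                   vapply(vcf_rows, function(r)
                     paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", ".", ".",
                           sep = "\t"), ""))
    writeLines(vcf_lines, vcf_path)

    # --- HGVS list across flavors (all parse-valid) ---------------------
    cds <- man$coding_cds
    at <- function(b) substr(ref_sequence(db, "TXCOD1"), b + 1L, b + 1L)
    donor_g <- project_to_primary(db, "TXCOD1", 599L, 600L)  # last exon1 base
    intron1_base <- substr(genome, donor_g$end + 1L, donor_g$end + 1L)
    acceptor_gbase <- substr(genome, 800L, 800L)             # base before exon 2
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    hgvs <- c(
      vapply(seq_len(10L), function(i) {
        r <- vcf_rows[[i]]
        a <- parse_vcf_record(db, r$chrom, r$pos, r$ref, r$alt)
        format_hgvs(db, a, "g")
      }, ""),
      sprintf("TXCOD1:c.736A>%s", c("C", "T")),
      sprintf("TXCOD1:c.10%s>%s", at(cds[1] + 9L), other(at(cds[1] + 9L))),
      sprintf("TXCOD1:c.-5%s>%s", at(cds[1] - 5L), other(at(cds[1] - 5L))),
      sprintf("TXCOD1:c.*8%s>%s", at(cds[2] + 7L), other(at(cds[2] + 7L))),
      sprintf("TXCOD1:c.%d+1%s>%s", man$donor_c, intron1_base, other(intron1_base)),
      sprintf("TXCOD1:c.%d-1%s>%s", man$acceptor_c, acceptor_gbase,
              other(acceptor_gbase)),
      "TXCOD1:c.20_22del", "TXCOD1:c.30_31insACT", "TXCOD1:c.40_42dup",
      "TXCOD1:c.50_53inv", "TXCOD1:c.60_62delinsT",
      sprintf("TXE1:n.15%s>%s", substr(ref_sequence(db, "TXE1"), 15L, 15L),
              other(substr(ref_sequence(db, "TXE1"), 15L, 15L))),
      sprintf("TXMIN1:c.30%s>%s", at2(db, "TXMIN1", min_b = 49L),
              other(at2(db, "TXMIN1", min_b = 49L))),
      sprintf("TXGR1:c.%ddelG", man$grun_c),
      sprintf("TXGR1:c.%d-1delG", man$grun_c)
    )
    hgvs_path <- file.path(dir, "hgvs.txt")
    writeLines(hgvs, hgvs_path)

    # --- assertion and frequency tables over Met->Leu pairs -------------
    met <- man$met_codons
    pair_hgvs <- function(codon) {
      pos <- 3L * (codon - 1L) + 1L      # c-position of the codon's A
      sprintf("TXCOD1:c.%dA>%s", pos, c("C", "T"))
    }
    ap <- spec$assertion_pairs
    plan <- c(rep("benign_uncertain", ap[["benign_uncertain"]]),
              rep("uncertain_pathogenic", ap[["uncertain_pathogenic"]]),
              rep("benign_benign", ap[["benign_benign"]]),
              rep("uncertain_uncertain", ap[["uncertain_uncertain"]]),
              rep("pathogenic_pathogenic", ap[["pathogenic_pathogenic"]]))
    cls <- list(benign_uncertain = c("benign", "uncertain"),
                uncertain_pathogenic = c("uncertain", "pathogenic"),
                benign_benign = c("likely-benign", "benign"),
                uncertain_uncertain = c("uncertain", "uncertain"),
                pathogenic_pathogenic = c("likely-pathogenic", "pathogenic"))
    arows <- data.frame(hgvs = pair_hgvs(246L),
                        classification = c("uncertain", "likely-pathogenic"),
                        stringsAsFactors = FALSE)
    for (i in seq_along(plan)) {
      arows <- rbind(arows, data.frame(hgvs = pair_hgvs(met[i]),
                                       classification = cls[[plan[i]]],
                                       stringsAsFactors = FALSE))
    }
    assertions_path <- file.path(dir, "assertions.tsv")
    utils::write.table(arows, assertions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    exp_mat <- matrix(0L, 3, 3, dimnames = list(
      c("benign", "uncertain", "pathogenic"),
      c("benign", "uncertain", "pathogenic")))
    exp_mat["uncertain", "benign"] <- ap[["benign_uncertain"]]
    exp_mat["pathogenic", "uncertain"] <- ap[["uncertain_pathogenic"]] + 1L
    exp_mat["benign", "benign"] <- ap[["benign_benign"]]
    exp_mat["uncertain", "uncertain"] <- ap[["uncertain_uncertain"]]
    exp_mat["pathogenic", "pathogenic"] <- ap[["pathogenic_pathogenic"]]

    fmet <- met[seq.int(length(plan) + 1L, length(plan) + spec$n_frequency_groups)]
    frows <- list()
    for (i in seq_along(fmet)) {
      hp <- pair_hgvs(fmet[i])
      af <- if (i <= spec$planted_discordant_groups) c(0.005, 0.06)
            else c(0.02, 0.04)
      frows[[i]] <- data.frame(hgvs = hp, af = sprintf("%.4f", af),
                               stringsAsFactors = FALSE)
    }
    frows <- do.call(rbind, frows)
    frequencies_path <- file.path(dir, "frequencies.tsv")
    utils::write.table(frows, frequencies_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth <- list(
      n_vcf_records = length(vcf_rows),
      n_valid = spec$n_variants,
      n_invalid = spec$n_invalid,
      planted_duplicates = spec$planted_duplicates,
      duplicate_pairs = dup_pairs,
      invalid_records = inv_idx,
      met_pair_hgvs = pair_hgvs(246L),
      assertion_matrix = exp_mat,
      n_assertion_pairs = length(plan) + 1L,
      n_frequency_groups = spec$n_frequency_groups,
      planted_discordant_groups = spec$planted_discordant_groups,
      n_hgvs = length(hgvs)
    )
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(vcf = vcf_path, hgvs = hgvs_path, assertions = assertions_path,
         frequencies = frequencies_path,
         truth_path = file.path(dir, "truth.json"), truth = truth)
  })
}

at2 <- function(db, ref_id, min_b) {
  s <- ref_sequence(db, ref_id)
  substr(s, min_b + 1L, min_b + 1L)
}
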