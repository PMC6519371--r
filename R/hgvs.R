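# HGVS parsing/formatting and VCF record intake.
#
# Supported grammar: <ref>:(g|c|n).<pos-spec><edit> with edits
# REF>ALT, del[SEQ], insSEQ, dup[SEQ], delinsSEQ, inv; positions support
# ranges (A_B), intron offsets (N+k / N-k) and UTR anchors (-N, *N) for c..
# Haplotype syntax (c.[x;y]) is recognized and rejected as unsupported.
# Internally everything is zero-based half-open interbase; HGVS I/O converts
# to and from 1-based inclusive numbering.

POS_RE <- "([-*]?[0-9]+(?:[+-][0-9]+)?)"

hgvs_patterns <- function() {
  p <- POS_RE
  list(
    delins = paste0("^", p, "(?:_", p, ")?delins([ACGT]+)$"),
    ins    = paste0("^", p, "_", p, "ins([ACGT]+)$"),
    inv    = paste0("^", p, "(?:_", p, ")?inv$"),
    dup    = paste0("^", p, "(?:_", p, ")?dup([ACGT]*)$"),
    del    = paste0("^", p, "(?:_", p, ")?del([ACGT]*)$"),
    sub    = paste0("^", p, "([ACGT])>([ACGT])$")
  )
}

match_groups <- function(re, x) {
  m <- regexec(re, x)[[1]]
  if (m[1] == -1) return(NULL)
  regmatches(x, list(m))[[1]][-1]
}

#' Parse an HGVS expression into a validated contextual allele
#'
#' Substitutions, deletions, insertions, duplications, delins and inversions
#' on g./c./n. numbering are supported, including intron offsets for
#' transcript numbering. Duplications are rewritten as insertion of the
#' duplicated span at its 3' edge; inversions as delins of the reverse
#' complement. Exonic c./n. variants are expressed on the transcript record;
#' variants touching intronic positions are expressed on the primary assembly
#' (the transcript itself contains no intronic bases). The stated reference
#' allele, when present, is checked against the reference sequence.
#'
#' @param db An `allele_refdb`.
#' @param expr HGVS expression, e.g. `"TOY1:g.5T>A"`.
#' @return A trimmed, validated `contextual_allele`.
#' @export
parse_hgvs <- function(db, expr) {
  expr <- trimws(expr)
  m <- match_groups("^([A-Za-z][A-Za-z0-9_.-]*):([gcn])\\.(.+)$", expr)
  if (is.null(m))
    areg_abort("areg_syntax", sprintf("not a recognizable HGVS expression: %s", expr))
  ref_id <- m[1]; num <- m[2]; body <- m[3]
  if (startsWith(body, "["))
    areg_abort("areg_not_supported",
               sprintf("haplotype expressions are not supported: %s", expr))
  rec <- refdb_record(db, ref_id)
  if (num == "g" && rec$kind == "transcript")
    areg_abort("areg_unsupported_numbering",
               sprintf("g. numbering on transcript %s", ref_id))
  if (num != "g" && rec$kind != "transcript")
    areg_abort("areg_unsupported_numbering",
               sprintf("%s. numbering on non-transcript %s", num, ref_id))

  pats <- hgvs_patterns()
  edit <- NULL; g <- NULL
  for (nm in names(pats)) {
    g <- match_groups(pats[[nm]], body)
    if (!is.null(g)) { edit <- nm; break }
  }
  if (is.null(edit))
    areg_abort("areg_syntax", sprintf("cannot parse variant description: %s", body))

  tok1 <- parse_pos_token(g[1])
  tok2 <- if (nm_has_range(edit) && nzchar(g[2])) parse_pos_token(g[2]) else tok1
  seqarg <- hgvs_seq_arg(edit, g)

  if (num == "g") {
    if (tok1$offset != 0L || tok2$offset != 0L || nzchar(tok1$region) || nzchar(tok2$region))
      areg_abort("areg_syntax", "g. positions take no intron offset or UTR sign")
    b1 <- tok1$n - 1L; b2 <- tok2$n - 1L
    if (b1 < 0L || b2 < b1)
      areg_abort("areg_position", sprintf("invalid position range in %s", expr))
    return(build_edit(db, ref_id, b1, b2, edit, seqarg, minus = FALSE))
  }

  if (tok1$offset == 0L && tok2$offset == 0L) {
    b1 <- tx_base_for_number(rec, num, tok1$region, tok1$n)
    b2 <- tx_base_for_number(rec, num, tok2$region, tok2$n)
    if (b1 < 0L || b2 < b1)
      areg_abort("areg_position", sprintf("invalid position range in %s", expr))
    L <- nchar(ref_sequence(db, ref_id))
    if (b2 >= L)
      areg_abort("areg_position", sprintf("position beyond end of %s", ref_id))
    return(build_edit(db, ref_id, b1, b2, edit, seqarg, minus = FALSE))
  }

  # intron-touching: resolve endpoint bases on the primary assembly
  r1 <- resolve_transcript_position(db, ref_id, g[1], num)
  r2 <- if (nm_has_range(edit) && nzchar(g[2]))
          resolve_transcript_position(db, ref_id, g[2], num) else r1
  minus <- rec$strand == "-"
  lo <- min(r1$base, r2$base); hi <- max(r1$base, r2$base)
  target <- rec$alignment$target_ref_id
  build_edit(db, target, lo, hi, edit, seqarg, minus = minus)
}

nm_has_range <- function(edit) edit != "sub"

hgvs_seq_arg <- function(edit, g) {
  switch(edit,
         sub = c(g[2], g[3]),
         delins = g[3],
         ins = g[3],
         dup = g[3],
         del = g[3],
         inv = "")
}

# Build, validate and trim the edit over bases b1..b2 (inclusive, in the
# coordinate space of ref_id). `minus` marks that the expression was written
# in the orientation opposite to ref_id (transcript on the minus strand whose
# intronic variant lands on the genome): stated sequences are then
# reverse-complemented and the duplication anchor flips to the genomic start.
build_edit <- function(db, ref_id, b1, b2, edit, seqarg, minus) {
  seq <- ref_sequence(db, ref_id)
  orient <- function(x) if (minus) revcomp(x) else x
  span_slice <- substr(seq, b1 + 1L, b2 + 1L)
  a <- switch(edit,
    sub = {
      if (b2 != b1)
        areg_abort("areg_syntax", "substitutions take a single position")
      contextual_allele(ref_id, b1, b1 + 1L, orient(seqarg[1]), orient(seqarg[2]))
    },
    del = {
      stated <- seqarg
      ref <- if (nzchar(stated)) orient(stated) else span_slice
      contextual_allele(ref_id, b1, b2 + 1L, ref, "")
    },
    ins = {
      if (b2 != b1 + 1L)
        areg_abort("areg_syntax", "insertion positions must be adjacent")
      contextual_allele(ref_id, b1 + 1L, b1 + 1L, "", orient(seqarg))
    },
    dup = {
      if (nzchar(seqarg) && orient(seqarg) != span_slice)
        areg_abort("areg_reference_mismatch",
                   sprintf("stated duplicated sequence %s does not match reference %s",
                           seqarg, if (minus) revcomp(span_slice) else span_slice))
      anchor <- if (minus) b1 else b2 + 1L
      contextual_allele(ref_id, anchor, anchor, "", span_slice)
    },
    inv = {
      if (b2 == b1)
        areg_abort("areg_syntax", "inversions require a range of length >= 2")
      contextual_allele(ref_id, b1, b2 + 1L, span_slice, revcomp(span_slice))
    },
    delins = contextual_allele(ref_id, b1, b2 + 1L, span_slice, orient(seqarg))
  )
  validate_allele(db, a)
  trim_allele(a)
}

#' Parse a VCF-style record into a validated contextual allele
#'
#' The anchor-base convention of VCF is undone by trimming shared leading and
#' trailing bases, so the result is the minimal contextual allele and is
#' identical to parsing the corresponding HGVS expression.
#'
#' @param db An `allele_refdb`.
#' @param chrom Reference label (CHROM).
#' @param pos_1based 1-based POS.
#' @param ref_field,alt_field REF and ALT fields (non-empty base strings).
#' @return A trimmed, validated `contextual_allele`.
#' @export
parse_vcf_record <- function(db, chrom, pos_1based, ref_field, alt_field) {
  ref_field <- toupper(ref_field); alt_field <- toupper(alt_field)
  if (!nzchar(ref_field) || !nzchar(alt_field))
    areg_abort("areg_syntax", "VCF REF and ALT must be non-empty")
  if (grepl("[^ACGTN]", ref_field) || grepl("[^ACGT]", alt_field))
    areg_abort("areg_not_supported",
               sprintf("unsupported VCF allele: %s>%s", ref_field, alt_field))
  pos <- as.integer(pos_1based)
  if (is.na(pos) || pos < 1L)
    areg_abort("areg_position", "VCF POS must be a positive integer")
  a <- contextual_allele(chrom, pos - 1L, pos - 1L + nchar(ref_field),
                         ref_field, alt_field)
  validate_allele(db, a)
  trim_allele(a)
}

#' Format a contextual allele as an HGVS expression
#'
#' Emits the allele as given; placement (e.g. the 3' rule for shiftable
#' indels) is the caller's responsibility via [normalize_allele()].
#'
#' @param db An `allele_refdb`.
#' @param allele A `contextual_allele`.
#' @param numbering `"g"`, `"c"` or `"n"`; defaults to the natural numbering
#'   of the allele's reference record.
#' @return HGVS expression string.
#' @export
format_hgvs <- function(db, allele, numbering = NULL) {
  rec <- refdb_record(db, allele$ref_id)
  if (is.null(numbering))
    numbering <- if (rec$kind == "transcript") {
      if (is.null(rec$cds)) "n" else "c"
    } else "g"
  if (numbering == "g" && rec$kind == "transcript")
    areg_abort("areg_unsupported_numbering", "g. numbering on a transcript")
  if (numbering != "g" && rec$kind != "transcript")
    areg_abort("areg_unsupported_numbering",
               sprintf("%s. numbering on non-transcript %s", numbering, allele$ref_id))
  P <- function(b) {
    if (numbering == "g") as.character(b + 1L)
    else number_for_tx_base(rec, numbering, b)
  }
  a <- allele
  head <- paste0(a$ref_id, ":", numbering, ".")
  nr <- nchar(a$ref); na <- nchar(a$alt)
  if (nr == 1L && na == 1L)
    return(paste0(head, P(a$start), a$ref, ">", a$alt))
  if (na == 0L) {
    return(paste0(head, if (nr == 1L) P(a$start)
                        else paste0(P(a$start), "_", P(a$end - 1L)), "del"))
  }
  if (nr == 0L) {
    if (a$start == 0L)
      areg_abort("areg_position",
                 "insertion before the first base cannot be written in HGVS")
    return(paste0(head, P(a$start - 1L), "_", P(a$start), "ins", a$alt))
  }
  paste0(head, if (nr == 1L) P(a$start)
               else paste0(P(a$start), "_", P(a$end - 1L)), "delins", a$alt)
}

#' Read a VCF file into contextual alleles
#'
#' Multi-allelic records are split per ALT. Records that fail parsing or
#' validation are kept in the report with their error message rather than
#' aborting the read.
#'
#' @param db An `allele_refdb`.
#' @param path VCF path.
#' @return A list with `table` (data.frame: chrom, pos, ref, alt, ok, error)
#'   and `alleles` (list of `contextual_allele` or `NULL` per row).
#' @export
read_vcf_alleles <- function(db, path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (alt in alts)
      rows[[length(rows) + 1L]] <- list(chrom = fix[i, "CHROM"],
                                        pos = as.integer(fix[i, "POS"]),
                                        ref = fix[i, "REF"], alt = alt)
  }
  parse_variant_rows(db, rows)
}

parse_variant_rows <- function(db, rows) {
  n <- length(rows)
  ok <- logical(n); err <- character(n); alleles <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rows[[i]]
    res <- tryCatch(parse_vcf_record(db, r$chrom, r$pos, r$ref, r$alt),
                    areg_error = function(e) e)
    if (is_areg_error(res)) { ok[i] <- FALSE; err[i] <- conditionMessage(res) }
    else { ok[i] <- TRUE; alleles[[i]] <- res }
  }
  list(table = data.frame(
         chrom = vapply(rows, `[[`, "", "chrom"),
         pos = vapply(rows, function(r) as.integer(r$pos), 0L),
         ref = vapply(rows, `[[`, "", "ref"),
         alt = vapply(rows, `[[`, "", "alt"),
         ok = ok, error = err, stringsAsFactors = FALSE),
       alleles = alleles)
}

#' Read a plain-text HGVS list (one expression per line)
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of expressions.
#' @export
read_hgvs_lines <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}
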