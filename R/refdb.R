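# Reference database: verbatim sequences plus alignment-encoded records.
# A non-primary record is stored as a transformation of the primary assembly:
# the target locus, a CIGAR over {M,I,D}, the substituted/inserted sequences
# in CIGAR order, and unaligned 5'/3' tails. Transcripts carry a strand, an
# exon structure and an optional CDS interval (transcript coordinates).
#
# CIGAR dialect: M consumes target and query (an M run with a non-empty
# substituted sequence replaces the target bases wholesale), I consumes query
# only (sequence supplied), D consumes target only (an intron, for
# transcripts). All encoding-side coordinates are on the plus strand of the
# target; a minus-strand transcript is the reverse complement of the edited
# target slice, with tails attached in transcript orientation.

#' Create an alignment encoding
#'
#' @param target_ref_id Label of the primary-assembly sequence aligned to.
#' @param target_start,target_end Interbase interval on the target.
#' @param cigar CIGAR string over M/I/D, e.g. `"120M85D240M"`.
#' @param subs Character vector with one entry per CIGAR operation: the
#'   inserted sequence for I, a same-length replacement for a substituted M
#'   run (or `""` for an identical match), `""` for D.
#' @param tail5,tail3 Unaligned leading/trailing sequence, in transcript
#'   orientation.
#' @return An `alignment_encoding` list.
#' @export
alignment_encoding <- function(target_ref_id, target_start, target_end,
                               cigar, subs = NULL, tail5 = "", tail3 = "") {
  ops <- parse_cigar(cigar)
  if (is.null(subs)) subs <- rep("", nrow(ops))
  if (length(subs) != nrow(ops))
    areg_abort("areg_spec", "substituted_seqs must have one entry per CIGAR op")
  subs <- toupper(subs)
  target_start <- as.integer(target_start); target_end <- as.integer(target_end)
  t_len <- sum(ops$len[ops$op %in% c("M", "D")])
  if (t_len != target_end - target_start)
    areg_abort("areg_spec", sprintf(
      "CIGAR consumes %d target bases but target interval has length %d",
      t_len, target_end - target_start))
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] == "I" && nchar(subs[i]) != ops$len[i])
      areg_abort("areg_spec", "insertion length disagrees with CIGAR")
    if (ops$op[i] == "M" && nzchar(subs[i]) && nchar(subs[i]) != ops$len[i])
      areg_abort("areg_spec", "substituted M run length disagrees with CIGAR")
    if (ops$op[i] == "D" && nzchar(subs[i]))
      areg_abort("areg_spec", "D operations carry no sequence")
  }
  structure(list(target_ref_id = target_ref_id,
                 target_start = target_start, target_end = target_end,
                 ops = ops, subs = subs,
                 tail5 = toupper(tail5), tail3 = toupper(tail3)),
            class = "alignment_encoding")
}

parse_cigar <- function(cigar) {
  if (!grepl("^([0-9]+[MID])+$", cigar))
    areg_abort("areg_spec", sprintf("malformed CIGAR: %s", cigar))
  m <- gregexpr("[0-9]+[MID]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(op = substr(toks, nchar(toks), nchar(toks)),
             len = as.integer(substr(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

format_cigar <- function(ops) paste0(ops$len, ops$op, collapse = "")

#' Create a reference record
#'
#' @param ref_id Accession-like label.
#' @param kind One of `"genomic-primary"`, `"genomic-other"`, `"transcript"`.
#' @param seq Verbatim sequence, or `NULL` when `alignment` is given.
#' @param alignment An [alignment_encoding()], or `NULL` for verbatim records.
#' @param strand `"+"` or `"-"` (transcripts only).
#' @param cds Optional CDS interval `c(start, end)` in transcript interbase
#'   coordinates.
#' @param exons Optional two-column matrix of exon intervals in transcript
#'   interbase coordinates; derived from the alignment when omitted.
#' @param gene Optional gene symbol.
#' @return A `ref_record` list.
#' @export
ref_record <- function(ref_id, kind = c("genomic-primary", "genomic-other",
                                        "transcript"),
                       seq = NULL, alignment = NULL, strand = "+",
                       cds = NULL, exons = NULL, gene = NA_character_) {
  kind <- match.arg(kind)
  if (is.null(seq) == is.null(alignment))
    areg_abort("areg_spec",
               "exactly one of a verbatim sequence or an alignment is required")
  if (!strand %in% c("+", "-"))
    areg_abort("areg_spec", "strand must be '+' or '-'")
  if (!is.null(seq)) {
    seq <- toupper(seq)
    if (grepl("[^ACGTN]", seq))
      areg_abort("areg_spec", "sequence contains characters outside {A,C,G,T,N}")
  }
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    if (length(cds) != 2L || cds[1] < 0L || cds[2] <= cds[1] ||
        (cds[2] - cds[1]) %% 3L != 0L)
      areg_abort("areg_spec", "CDS must be a positive multiple of 3 in length")
  }
  structure(list(ref_id = ref_id, kind = kind, seq = seq,
                 alignment = alignment, strand = strand, cds = cds,
                 exons = exons, gene = gene),
            class = "ref_record")
}

#' Create a reference database
#'
#' @param primary Label of the primary assembly sequence.
#' @param records List of [ref_record()] objects (the primary must be one of
#'   them, stored verbatim).
#' @return An `allele_refdb` environment.
#' @export
refdb <- function(primary, records = list()) {
  db <- new.env(parent = emptyenv())
  db$primary <- primary
  db$records <- list()
  db$seqcache <- new.env(parent = emptyenv())
  class(db) <- "allele_refdb"
  for (r in records) refdb_add(db, r)
  db
}

#' Add a record to a reference database
#' @param db An `allele_refdb`.
#' @param record A [ref_record()].
#' @return The database, invisibly.
#' @export
refdb_add <- function(db, record) {
  stopifnot(inherits(record, "ref_record"))
  db$records[[record$ref_id]] <- record
  if (exists(record$ref_id, envir = db$seqcache))
    rm(list = record$ref_id, envir = db$seqcache)
  invisible(db)
}

#' @export
print.allele_refdb <- function(x, ...) {
  kinds <- vapply(x$records, `[[`, "", "kind")
  cat(sprintf("<reference database> primary=%s, %d records (%d transcripts)\n",
              x$primary, length(x$records), sum(kinds == "transcript")))
  invisible(x)
}

refdb_record <- function(db, ref_id) {
  rec <- db$records[[ref_id]]
  if (is.null(rec))
    areg_abort("areg_unknown_reference", sprintf("unknown reference: %s", ref_id))
  rec
}

#' List reference identifiers
#' @param db An `allele_refdb`.
#' @param kind Optional filter on record kind.
#' @param gene Optional filter on gene symbol.
#' @return Character vector of ref_ids.
#' @export
ref_ids <- function(db, kind = NULL, gene = NULL) {
  ids <- names(db$records)
  if (!is.null(kind))
    ids <- ids[vapply(db$records[ids], `[[`, "", "kind") == kind]
  if (!is.null(gene)) {
    g <- vapply(db$records[ids], `[[`, "", "gene")
    ids <- ids[!is.na(g) & g == gene]
  }
  ids
}

#' Reconstruct the full sequence of a reference record
#'
#' Verbatim records return their sequence; alignment-encoded records are
#' rebuilt by walking the CIGAR over the target slice, applying substituted
#' and inserted sequences, reverse-complementing for minus-strand records and
#' attaching the unaligned tails.
#'
#' @param db An `allele_refdb`.
#' @param ref_id Reference label.
#' @return Character scalar sequence over {A,C,G,T,N}.
#' @export
reconstruct_sequence <- function(db, ref_id) {
  rec <- refdb_record(db, ref_id)
  if (!is.null(rec$seq)) return(rec$seq)
  aln <- rec$alignment
  if (is.null(db$records[[aln$target_ref_id]]))
    areg_abort("areg_missing_reference",
               sprintf("alignment of %s targets unknown reference %s",
                       ref_id, aln$target_ref_id))
  target <- ref_sequence(db, aln$target_ref_id)
  if (aln$target_end > nchar(target))
    areg_abort("areg_spec", "target interval beyond end of target sequence")
  pieces <- character(nrow(aln$ops))
  t <- aln$target_start
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "M") {
      pieces[i] <- if (nzchar(aln$subs[i])) aln$subs[i]
                   else substr(target, t + 1L, t + len)
      t <- t + len
    } else if (op == "I") {
      pieces[i] <- aln$subs[i]
    } else { # D
      t <- t + len
    }
  }
  aligned <- paste0(pieces, collapse = "")
  body <- if (rec$strand == "-") revcomp(aligned) else aligned
  paste0(aln$tail5, body, aln$tail3)
}

#' Get (and cache) the full sequence of a reference
#' @inheritParams reconstruct_sequence
#' @return Character scalar sequence.
#' @export
ref_sequence <- function(db, ref_id) {
  if (exists(ref_id, envir = db$seqcache))
    return(get(ref_id, envir = db$seqcache))
  seq <- reconstruct_sequence(db, ref_id)
  assign(ref_id, seq, envir = db$seqcache)
  seq
}

# ---- alignment geometry ----------------------------------------------------

# Per-op coordinates: qs/qe in aligned-query (plus-orientation, tail-free)
# coordinates, ts/te on the target.
aln_blocks <- function(aln) {
  n <- nrow(aln$ops)
  qs <- qe <- ts <- te <- integer(n)
  q <- 0L; t <- aln$target_start
  for (i in seq_len(n)) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    qs[i] <- q; ts[i] <- t
    if (op != "D") q <- q + len
    if (op != "I") t <- t + len
    qe[i] <- q; te[i] <- t
  }
  cbind(aln$ops, sub = aln$subs, qs = qs, qe = qe, ts = ts, te = te)
}

aln_query_len <- function(aln) sum(aln$ops$len[aln$ops$op != "D"])

# Geometry bundle for a transcript/other record.
rec_geom <- function(db, rec) {
  aln <- rec$alignment
  list(aln = aln, blocks = aln_blocks(aln),
       n5 = nchar(aln$tail5), n3 = nchar(aln$tail3),
       A = aln_query_len(aln))
}

# Transcript interbase point -> aligned-query (plus-orientation) point.
tx_point_to_q <- function(rec, g, p) {
  if (p < g$n5 || p > g$n5 + g$A)
    areg_abort("areg_unalignable",
               sprintf("position %d of %s lies in an unaligned tail", p, rec$ref_id))
  if (rec$strand == "-") g$A - (p - g$n5) else p - g$n5
}

# Transcript base index -> aligned-query base index.
tx_base_to_qb <- function(rec, g, b) {
  if (b < g$n5 || b >= g$n5 + g$A)
    areg_abort("areg_unalignable",
               sprintf("base %d of %s lies in an unaligned tail", b, rec$ref_id))
  if (rec$strand == "-") g$A - 1L - (b - g$n5) else b - g$n5
}

# Aligned-query base -> target base. strict rejects substituted M runs.
qb_to_target_base <- function(rec, g, qb, strict = TRUE) {
  bl <- g$blocks
  for (i in seq_len(nrow(bl))) {
    if (bl$op[i] == "D") next
    if (qb >= bl$qs[i] && qb < bl$qe[i]) {
      if (bl$op[i] == "I")
        areg_abort("areg_unprojectable",
                   sprintf("base %d of %s is transcript-only (insertion in query)",
                           qb, rec$ref_id))
      if (strict && nzchar(bl$sub[i]))
        areg_abort("areg_unprojectable",
                   sprintf("base %d of %s lies in a substituted alignment run",
                           qb, rec$ref_id))
      return(bl$ts[i] + (qb - bl$qs[i]))
    }
  }
  areg_abort("areg_unalignable", "base outside aligned portion")
}

#' Project an interval on a reference onto the primary assembly
#'
#' Nonzero-length intervals must lie wholly within one unedited match run of
#' the alignment; intervals that overlap an insertion, deletion or
#' substituted run are refused (`areg_unprojectable`). Zero-length intervals
#' (insertion anchors) at an exon-exon junction map to the genomic interbase
#' point at the 3' end of the upstream exon in transcript orientation.
#'
#' @param db An `allele_refdb`.
#' @param ref_id Reference label.
#' @param start,end Interbase interval on that reference.
#' @return List with `ref_id` (the primary), `start`, `end`, `strand`.
#' @export
project_to_primary <- function(db, ref_id, start, end) {
  rec <- refdb_record(db, ref_id)
  start <- as.integer(start); end <- as.integer(end)
  if (rec$kind == "genomic-primary")
    return(list(ref_id = ref_id, start = start, end = end, strand = "+"))
  if (is.null(rec$alignment))
    areg_abort("areg_unalignable",
               sprintf("%s has no alignment to the primary assembly", ref_id))
  g <- rec_geom(db, rec)
  target <- rec$alignment$target_ref_id
  if (end > start) {
    qb1 <- tx_base_to_qb(rec, g, start)
    qb2 <- tx_base_to_qb(rec, g, end - 1L)
    qlo <- min(qb1, qb2); qhi <- max(qb1, qb2)
    bl <- g$blocks
    hit <- which(bl$op == "M" & bl$qs <= qlo & qhi < bl$qe)
    if (length(hit) != 1L)
      areg_abort("areg_unprojectable",
                 sprintf("interval [%d,%d) of %s spans an alignment edit",
                         start, end, ref_id))
    if (nzchar(bl$sub[hit]))
      areg_abort("areg_unprojectable",
                 sprintf("interval [%d,%d) of %s overlaps a substituted run",
                         start, end, ref_id))
    gs <- bl$ts[hit] + (qlo - bl$qs[hit])
    ge <- bl$ts[hit] + (qhi - bl$qs[hit]) + 1L
    return(list(ref_id = target, start = gs, end = ge, strand = rec$strand))
  }
  # insertion anchor
  q <- tx_point_to_q(rec, g, start)
  bl <- g$blocks
  cand <- integer(0)
  for (i in seq_len(nrow(bl))) {
    if (bl$op[i] == "I" && bl$qs[i] < q && q < bl$qe[i])
      areg_abort("areg_unprojectable",
                 "insertion anchor inside a transcript-only insertion")
    if (bl$op[i] == "M" && bl$qs[i] <= q && q <= bl$qe[i])
      cand <- c(cand, bl$ts[i] + (q - bl$qs[i]))
  }
  if (!length(cand))
    areg_abort("areg_unalignable", "point outside aligned portion")
  t <- if (rec$strand == "-") max(cand) else min(cand)
  list(ref_id = target, start = t, end = t, strand = rec$strand)
}

#' Project an interval on the primary assembly into a reference's coordinates
#'
#' Inverse of [project_to_primary()]; identity holds on every interval that
#' does not overlap an alignment edit.
#'
#' @param db An `allele_refdb`.
#' @param ref_id Reference to project into.
#' @param start,end Interbase interval on the primary assembly.
#' @return List with `ref_id`, `start`, `end` in that reference's coordinates.
#' @export
project_from_primary <- function(db, ref_id, start, end) {
  rec <- refdb_record(db, ref_id)
  start <- as.integer(start); end <- as.integer(end)
  if (rec$kind == "genomic-primary")
    return(list(ref_id = ref_id, start = start, end = end))
  if (is.null(rec$alignment))
    areg_abort("areg_unalignable",
               sprintf("%s has no alignment to the primary assembly", ref_id))
  g <- rec_geom(db, rec)
  bl <- g$blocks
  qb_to_tx <- function(qb)
    if (rec$strand == "-") g$n5 + (g$A - 1L - qb) else g$n5 + qb
  if (end > start) {
    hit <- which(bl$op == "M" & bl$ts <= start & end <= bl$te &
                   !nzchar(bl$sub))
    if (length(hit) != 1L)
      areg_abort("areg_unprojectable",
                 sprintf("interval [%d,%d) spans an alignment edit of %s",
                         start, end, ref_id))
    b1 <- qb_to_tx(bl$qs[hit] + (start - bl$ts[hit]))
    b2 <- qb_to_tx(bl$qs[hit] + (end - 1L - bl$ts[hit]))
    return(list(ref_id = ref_id, start = min(b1, b2), end = max(b1, b2) + 1L))
  }
  cand <- integer(0)
  for (i in seq_len(nrow(bl))) {
    if (bl$op[i] == "M" && bl$ts[i] <= start && start <= bl$te[i]) {
      q <- bl$qs[i] + (start - bl$ts[i])
      p <- if (rec$strand == "-") g$n5 + (g$A - q) else g$n5 + q
      cand <- c(cand, p)
    }
  }
  if (!length(cand))
    areg_abort("areg_unprojectable",
               sprintf("point %d has no exonic image in %s", start, ref_id))
  p <- min(cand)
  list(ref_id = ref_id, start = p, end = p)
}

# ---- exon structure and transcript numbering -------------------------------

#' Exon structure of a transcript, in transcript interbase coordinates
#' @param db An `allele_refdb`.
#' @param ref_id Transcript label.
#' @return Two-column integer matrix (start, end), 5' to 3'.
#' @export
transcript_exons <- function(db, ref_id) {
  rec <- refdb_record(db, ref_id)
  if (!is.null(rec$exons)) return(rec$exons)
  if (is.null(rec$alignment))
    areg_abort("areg_spec", sprintf("%s has no exon structure", ref_id))
  g <- rec_geom(db, rec)
  bl <- g$blocks
  # aligned-query runs between D ops, merged across M/I
  starts <- integer(0); ends <- integer(0)
  open <- NA_integer_
  for (i in seq_len(nrow(bl))) {
    if (bl$op[i] == "D") {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, bl$qs[i]); open <- NA_integer_ }
    } else if (is.na(open)) open <- bl$qs[i]
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, bl$qe[nrow(bl)]) }
  if (rec$strand == "-") {
    s2 <- g$A - rev(ends); e2 <- g$A - rev(starts)
    starts <- s2; ends <- e2
  }
  cbind(start = starts + g$n5, end = ends + g$n5)
}

# Map a c./n. number (region "", "-", "*") to a 0-based transcript base index.
tx_base_for_number <- function(rec, numbering, region, n) {
  if (numbering == "n") {
    if (nzchar(region))
      areg_abort("areg_syntax", "n. positions take no UTR region sign")
    return(n - 1L)
  }
  if (is.null(rec$cds))
    areg_abort("areg_unsupported_numbering",
               sprintf("%s has no CDS annotation; c. numbering unavailable",
                       rec$ref_id))
  if (region == "-") rec$cds[1] - n
  else if (region == "*") rec$cds[2] + n - 1L
  else rec$cds[1] + n - 1L
}

# Inverse: transcript base index -> printed c./n. number.
number_for_tx_base <- function(rec, numbering, b) {
  if (numbering == "n") return(as.character(b + 1L))
  if (is.null(rec$cds))
    areg_abort("areg_unsupported_numbering",
               sprintf("%s has no CDS annotation; c. numbering unavailable",
                       rec$ref_id))
  if (b < rec$cds[1]) paste0("-", rec$cds[1] - b)
  else if (b >= rec$cds[2]) paste0("*", b - rec$cds[2] + 1L)
  else as.character(b - rec$cds[1] + 1L)
}

#' Resolve a transcript position (with optional intron offset) to the genome
#'
#' `c.N+k` / `c.N-k` resolve to the genomic base `k` into the intron from the
#' donor/acceptor side of the anchor base, honoring strand. UTR anchors
#' (`c.-N`, `c.*N`) are supported.
#'
#' @param db An `allele_refdb`.
#' @param ref_id Transcript label.
#' @param pos Position token, e.g. `"1200"`, `"1200-1"`, `"-5"`, `"*3"`.
#' @param numbering `"c"` or `"n"`.
#' @return List with `base` (0-based genomic base index on the primary
#'   assembly), `strand`, and `tx_base` (`NA` for intronic positions).
#' @export
resolve_transcript_position <- function(db, ref_id, pos, numbering = "c") {
  rec <- refdb_record(db, ref_id)
  if (rec$kind != "transcript")
    areg_abort("areg_unsupported_numbering",
               sprintf("%s is not a transcript", ref_id))
  tok <- parse_pos_token(pos)
  b <- tx_base_for_number(rec, numbering, tok$region, tok$n)
  if (is.null(rec$alignment))
    areg_abort("areg_unalignable",
               sprintf("%s has no alignment to the primary assembly", ref_id))
  g <- rec_geom(db, rec)
  L <- g$n5 + g$A + g$n3
  if (b < 0L || b >= L)
    areg_abort("areg_position",
               sprintf("position %s outside transcript %s", pos, ref_id))
  qb <- tx_base_to_qb(rec, g, b)
  anchor_t <- qb_to_target_base(rec, g, qb, strict = FALSE)
  if (tok$offset == 0L)
    return(list(base = anchor_t, strand = rec$strand, tx_base = b))
  dirg <- if ((tok$offset > 0L) == (rec$strand == "+")) 1L else -1L
  t2 <- anchor_t + dirg * abs(tok$offset)
  # must fall in the nearest intron (D run) on that genomic side of the anchor
  bl <- g$blocks
  anchor_blk <- which(bl$op == "M" & bl$qs <= qb & qb < bl$qe)[1]
  ord <- if (dirg > 0L) seq(anchor_blk + 1L, nrow(bl)) else rev(seq_len(anchor_blk - 1L))
  if (anchor_blk == nrow(bl) && dirg > 0L) ord <- integer(0)
  if (anchor_blk == 1L && dirg < 0L) ord <- integer(0)
  intron <- NA_integer_
  for (i in ord) { if (bl$op[i] == "D") { intron <- i; break }; if (bl$op[i] == "M") break }
  if (is.na(intron) || t2 < bl$ts[intron] || t2 >= bl$te[intron])
    areg_abort("areg_invalid_position",
               sprintf("offset %+d from %s.%s of %s is not inside an intron",
                       tok$offset, numbering, pos, ref_id))
  list(base = t2, strand = rec$strand, tx_base = NA_integer_)
}

# "1200-1", "-5", "*3+2" -> list(region, n, offset)
parse_pos_token <- function(pos) {
  m <- regexec("^([-*]?)([0-9]+)([+-][0-9]+)?$", pos)[[1]]
  if (m[1] == -1)
    areg_abort("areg_syntax", sprintf("malformed position: %s", pos))
  parts <- regmatches(pos, list(regexec("^([-*]?)([0-9]+)([+-][0-9]+)?$", pos)[[1]]))[[1]]
  list(region = parts[2], n = as.integer(parts[3]),
       offset = if (nzchar(parts[4])) as.integer(parts[4]) else 0L)
}

# ---- bundle I/O -------------------------------------------------------------

ALN_COLS <- c("ref_id", "kind", "strand", "target_ref_id", "target_start",
              "target_end", "cigar", "substituted_seqs", "tail5", "tail3",
              "cds_start", "cds_end", "exon_starts", "exon_ends",
              "gene_symbol")

dot_na <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)
undot <- function(x) ifelse(x == ".", "", x)

alignment_row <- function(rec) {
  aln <- rec$alignment
  exons <- rec$exons
  data.frame(
    ref_id = rec$ref_id, kind = rec$kind, strand = rec$strand,
    target_ref_id = aln$target_ref_id,
    target_start = aln$target_start, target_end = aln$target_end,
    cigar = format_cigar(aln$ops),
    substituted_seqs = dot_na(paste(dot_na(aln$subs), collapse = ",")),
    tail5 = dot_na(aln$tail5), tail3 = dot_na(aln$tail3),
    cds_start = if (is.null(rec$cds)) "." else rec$cds[1],
    cds_end = if (is.null(rec$cds)) "." else rec$cds[2],
    exon_starts = if (is.null(exons)) "." else paste(exons[, 1], collapse = ","),
    exon_ends = if (is.null(exons)) "." else paste(exons[, 2], collapse = ","),
    gene_symbol = dot_na(rec$gene),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment table for alignment-encoded records
#' @param records List of [ref_record()]s carrying alignments.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(records, path) {
  rows <- do.call(rbind, lapply(records, alignment_row))
  utils::write.table(rows[ALN_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a reference bundle from a configuration file
#'
#' The configuration is a JSON object with fields `primary` (label of the
#' primary assembly sequence), `fasta` (one or more FASTA paths holding
#' verbatim sequences) and optionally `alignments` (a TSV of
#' alignment-encoded records). Relative paths resolve against the
#' configuration file's directory. Sequences are upper-cased on load.
#'
#' @param config_path Path to the JSON configuration.
#' @return An `allele_refdb`.
#' @export
load_reference_bundle <- function(config_path) {
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  base <- dirname(normalizePath(config_path))
  respath <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  recs <- list()
  for (fa in respath(cfg$fasta)) {
    ss <- Biostrings::readDNAStringSet(fa)
    for (i in seq_along(ss)) {
      id <- sub("\\s.*$", "", names(ss)[i])
      kind <- if (id == cfg$primary) "genomic-primary" else "genomic-other"
      recs[[id]] <- ref_record(id, kind, seq = as.character(ss[[i]]))
    }
  }
  if (is.null(recs[[cfg$primary]]))
    areg_abort("areg_missing_reference",
               sprintf("primary assembly %s not found in FASTA", cfg$primary))
  db <- refdb(cfg$primary, recs)
  if (!is.null(cfg$alignments)) {
    tab <- utils::read.table(respath(cfg$alignments), sep = "\t", header = TRUE,
                             colClasses = "character", quote = "")
    for (i in seq_len(nrow(tab))) {
      r <- tab[i, ]
      subs <- undot(strsplit(r$substituted_seqs, ",", fixed = TRUE)[[1]])
      if (r$substituted_seqs == ".") subs <- NULL
      aln <- alignment_encoding(r$target_ref_id, as.integer(r$target_start),
                                as.integer(r$target_end), r$cigar, subs,
                                tail5 = undot(r$tail5), tail3 = undot(r$tail3))
      cds <- if (r$cds_start == ".") NULL else
        c(as.integer(r$cds_start), as.integer(r$cds_end))
      exons <- if (r$exon_starts == ".") NULL else
        cbind(start = as.integer(strsplit(r$exon_starts, ",")[[1]]),
              end = as.integer(strsplit(r$exon_ends, ",")[[1]]))
      refdb_add(db, ref_record(r$ref_id, r$kind, alignment = aln,
                               strand = r$strand, cds = cds, exons = exons,
                               gene = if (r$gene_symbol == ".") NA_character_
                                      else r$gene_symbol))
    }
  }
  db
}
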