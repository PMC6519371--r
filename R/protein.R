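# Amino acid consequences computed on the fly from protein-coding transcript
# sequences. Nothing protein-level is stored or aligned: the CDS is
# translated before and after applying the nucleotide allele and the two
# proteins are diffed. Changes touching fewer than eight residues get a
# compact p.-style descriptor; larger ones are reported as out-of-window.
# The grouping key is the full alternate protein sequence, so two different
# nucleotide variants producing the same protein fall in one group.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

aa3 <- function(x) {
  if (!nzchar(x)) return("")
  paste(AA3[strsplit(x, "")[[1]]], collapse = "")
}

# Translate with the standard nuclear code, stopping at (and including) the
# first stop codon. Trailing bases short of a codon are dropped; the caller
# decides whether that matters.
translate_cds <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  aas[is.na(aas)] <- "X"
  stop_at <- which(aas == "*")
  if (length(stop_at)) aas <- aas[seq_len(stop_at[1])]
  paste(aas, collapse = "")
}

# Window above which an amino acid change is not described compactly.
AREG_AA_WINDOW <- 8L

#' Compute the amino acid consequence of a transcript allele
#'
#' Translates the coding sequence before and after applying the allele (for
#' frameshifts, translation of the alternate continues past the annotated
#' CDS end to the first novel stop) and diffs the two proteins. Synonymous
#' changes and variants outside the CDS have `kind = "none"`; single-residue
#' changes are `"substitution"`; changes spanning fewer than eight residues
#' are `"small-change"`; anything larger, an ablated start/stop without a
#' nearby novel stop, or a change running into an incomplete terminal codon
#' is `"out-of-window"`.
#'
#' @param db An `allele_refdb`.
#' @param allele A `contextual_allele` on a transcript with a CDS annotation.
#' @return A `protein_effect` list: `transcript_id`, `kind`,
#'   `change_descriptor`, `alt_protein` (full alternate amino acid sequence,
#'   the grouping key), `gene`.
#' @export
protein_consequence <- function(db, allele) {
  rec <- refdb_record(db, allele$ref_id)
  if (rec$kind != "transcript" || is.null(rec$cds))
    areg_abort("areg_no_cds",
               sprintf("%s is not a protein-coding transcript", allele$ref_id))
  validate_allele(db, allele)
  a <- trim_allele(allele)
  txseq <- ref_sequence(db, a$ref_id)
  cds <- rec$cds
  ref_cds <- substr(txseq, cds[1] + 1L, cds[2])
  ref_prot <- translate_cds(ref_cds)
  eff <- function(kind, desc, altp)
    structure(list(transcript_id = a$ref_id, kind = kind,
                   change_descriptor = desc, alt_protein = altp,
                   gene = rec$gene),
              class = "protein_effect")
  # outside the CDS: protein unchanged
  if (a$end <= cds[1] || a$start >= cds[2])
    return(eff("none", "p.=", sub("\\*$", "", ref_prot)))
  # a change straddling the CDS start shifts where translation begins in the
  # alternate transcript; no compact descriptor is attempted
  if (a$start < cds[1])
    return(eff("out-of-window", NA_character_, NA_character_))
  alt_tx <- apply_allele(txseq, a)
  # translate from the CDS start through the transcript end so frameshifts
  # and stop losses can find their novel stop
  alt_prot_full <- translate_cds(substr(alt_tx, cds[1] + 1L, nchar(alt_tx)))
  has_ref_stop <- endsWith(ref_prot, "*")
  has_alt_stop <- endsWith(alt_prot_full, "*")
  ref_p <- sub("\\*$", "", ref_prot)
  alt_p <- sub("\\*$", "", alt_prot_full)
  if (has_ref_stop && has_alt_stop && ref_p == alt_p)
    return(eff("none", "p.=", alt_p))
  if (!has_alt_stop || !has_ref_stop)
    return(eff("out-of-window", NA_character_, if (has_alt_stop) alt_p else NA_character_))
  # diff including the stop so stop-gains/losses count as changed residues
  r <- paste0(ref_p, "*"); q <- paste0(alt_p, "*")
  nr <- nchar(r); nq <- nchar(q)
  p <- 0L
  while (p < min(nr, nq) && substr(r, p + 1L, p + 1L) == substr(q, p + 1L, p + 1L))
    p <- p + 1L
  s <- 0L
  while (s < min(nr, nq) - p && substr(r, nr - s, nr - s) == substr(q, nq - s, nq - s))
    s <- s + 1L
  ref_seg <- substr(r, p + 1L, nr - s)
  alt_seg <- substr(q, p + 1L, nq - s)
  span <- max(nchar(ref_seg), nchar(alt_seg))
  if (span >= AREG_AA_WINDOW)
    return(eff("out-of-window", NA_character_, alt_p))
  desc <- protein_descriptor(ref_seg, alt_seg, p, nr)
  kind <- if (nchar(ref_seg) == 1L && nchar(alt_seg) == 1L) "substitution"
          else "small-change"
  eff(kind, desc, alt_p)
}

protein_descriptor <- function(ref_seg, alt_seg, prefix, nr) {
  i <- prefix + 1L                       # first changed residue, 1-based
  j <- prefix + nchar(ref_seg)           # last changed ref residue
  first <- function(seg) substr(seg, 1L, 1L)
  last <- function(seg) substr(seg, nchar(seg), nchar(seg))
  if (nchar(ref_seg) == 1L && nchar(alt_seg) == 1L)
    return(paste0("p.", aa3(ref_seg), i, aa3(alt_seg)))
  if (nchar(alt_seg) == 0L) {            # in-frame deletion
    if (nchar(ref_seg) == 1L)
      return(paste0("p.", aa3(ref_seg), i, "del"))
    return(paste0("p.", aa3(first(ref_seg)), i, "_", aa3(last(ref_seg)), j, "del"))
  }
  if (nchar(ref_seg) == 0L)              # in-frame insertion between i-1 and i
    return(paste0("p.", i - 1L, "_", i, "ins", aa3(alt_seg)))
  if (nchar(ref_seg) == 1L)
    return(paste0("p.", aa3(ref_seg), i, "delins", aa3(alt_seg)))
  paste0("p.", aa3(first(ref_seg)), i, "_", aa3(last(ref_seg)), j,
         "delins", aa3(alt_seg))
}

#' @export
print.protein_effect <- function(x, ...) {
  cat(sprintf("<protein effect> %s %s %s\n", x$transcript_id, x$kind,
              if (is.na(x$change_descriptor)) "" else x$change_descriptor))
  invisible(x)
}

#' Group variants by identical alternate protein sequence
#'
#' @param effects List of `protein_effect`s (one per nucleotide variant;
#'   names, if set, label the variants in the output).
#' @return A list with `groups` (all groups keyed by alternate protein
#'   sequence, each a vector of variant indices or names) and `shared`
#'   (only the groups with two or more members).
#' @export
group_by_protein_effect <- function(effects) {
  keys <- vapply(effects, function(e)
    if (is.na(e$alt_protein)) NA_character_ else e$alt_protein, "")
  labs <- names(effects)
  if (is.null(labs)) labs <- as.character(seq_along(effects))
  ok <- !is.na(keys)
  groups <- split(labs[ok], keys[ok])
  groups <- groups[order(names(groups))]
  list(groups = groups, shared = groups[lengths(groups) >= 2L])
}
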