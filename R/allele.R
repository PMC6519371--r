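# Contextual alleles: a variant anchored to one reference sequence, held in
# zero-based half-open interbase coordinates. [4,5) is the 5th base; [4,4) is
# the insertion point between the 4th and 5th bases.

#' Create a contextual allele
#'
#' A contextual allele is a variant defined in the context of one reference
#' sequence: the reference label, an interbase interval on it, the reference
#' allele found there and the alternate allele replacing it.
#'
#' @param ref_id Reference sequence label.
#' @param start,end Zero-based half-open interbase interval; `end - start`
#'   must equal `nchar(ref)`. A zero-length interval is an insertion point.
#' @param ref Reference allele (may be `""` for insertions).
#' @param alt Alternate allele (may be `""` for deletions).
#' @return An object of class `contextual_allele`.
#' @examples
#' contextual_allele("TOY1", 4, 5, "T", "A")
#' @export
contextual_allele <- function(ref_id, start, end, ref = "", alt = "") {
  start <- as.integer(start); end <- as.integer(end)
  ref <- toupper(ref); alt <- toupper(alt)
  if (is.na(start) || is.na(end) || start < 0L || end < start)
    areg_abort("areg_position", sprintf("invalid interval [%s,%s)", start, end))
  if (end - start != nchar(ref))
    areg_abort("areg_position", "interval length does not match reference allele")
  if (!nzchar(ref) && !nzchar(alt))
    areg_abort("areg_position", "reference and alternate allele cannot both be empty")
  structure(
    list(ref_id = as.character(ref_id), start = start, end = end,
         ref = ref, alt = alt),
    class = "contextual_allele"
  )
}

#' @export
print.contextual_allele <- function(x, ...) {
  cat(sprintf("<contextual allele> %s [%d,%d) %s>%s\n", x$ref_id,
              x$start, x$end,
              if (nzchar(x$ref)) x$ref else "(empty)",
              if (nzchar(x$alt)) x$alt else "(empty)"))
  invisible(x)
}

#' @export
format.contextual_allele <- function(x, ...) {
  sprintf("%s:[%d,%d):%s>%s", x$ref_id, x$start, x$end, x$ref, x$alt)
}

allele_identical <- function(a, b) {
  a$ref_id == b$ref_id && a$start == b$start && a$end == b$end &&
    a$ref == b$ref && a$alt == b$alt
}

#' Apply a contextual allele to a reference sequence
#'
#' Splices the alternate allele into the reference character sequence,
#' yielding the full alternate sequence.
#'
#' @param seq Reference character sequence the allele's interval indexes into.
#' @param allele A `contextual_allele`.
#' @return The alternate full sequence (character scalar).
#' @export
apply_allele <- function(seq, allele) {
  n <- nchar(seq)
  if (allele$end > n)
    areg_abort("areg_position", "allele interval beyond sequence end")
  paste0(substr(seq, 1L, allele$start), allele$alt,
         substr(seq, allele$end + 1L, n))
}

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Maximal nucleotide allele size accepted for registration.
AREG_MAX_ALLELE <- 10000L

check_allele_size <- function(allele) {
  if (max(nchar(allele$ref), nchar(allele$alt)) > AREG_MAX_ALLELE)
    areg_abort("areg_size_limit",
               sprintf("allele longer than %d bases", AREG_MAX_ALLELE))
  invisible(allele)
}

#' Validate a contextual allele against its reference sequence
#'
#' Checks that the interval lies within the reference, that the stated
#' reference allele matches the sequence at that interval, that it does not
#' overlap ambiguous (N) bases, that the variant actually alters the
#' sequence, and that it respects the registration size cutoff.
#'
#' @param db An `allele_refdb`.
#' @param allele A `contextual_allele`.
#' @return The allele, invisibly, on success; otherwise a classed error.
#' @export
validate_allele <- function(db, allele) {
  seq <- ref_sequence(db, allele$ref_id)
  if (allele$end > nchar(seq))
    areg_abort("areg_position",
               sprintf("interval [%d,%d) beyond end of %s (length %d)",
                       allele$start, allele$end, allele$ref_id, nchar(seq)))
  slice <- substr(seq, allele$start + 1L, allele$end)
  if (grepl("N", slice, fixed = TRUE))
    areg_abort("areg_ambiguous_base",
               "reference allele overlaps ambiguous (N) bases")
  if (slice != allele$ref)
    areg_abort("areg_reference_mismatch",
               sprintf("reference allele mismatch on %s at [%d,%d): stated %s, found %s",
                       allele$ref_id, allele$start, allele$end,
                       if (nzchar(allele$ref)) allele$ref else "(empty)", slice))
  if (grepl("[^ACGT]", allele$alt))
    areg_abort("areg_syntax", "alternate allele contains non-ACGT characters")
  if (allele$ref == allele$alt)
    areg_abort("areg_position", "variant does not alter the sequence")
  check_allele_size(allele)
  invisible(allele)
}
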