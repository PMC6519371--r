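# Normalization: trimming to minimal form and shifting pure insertions or
# deletions through repetitive context. Left-aligned = cannot be shifted
# further 5'; right-aligned = cannot be shifted further 3'. The left-aligned
# form is the grouping key for canonicalization; the right-aligned form
# backs 3'-rule HGVS output.

#' Trim a contextual allele to minimal form
#'
#' Removes bases shared between the reference and alternate alleles, first
#' from the left, then from the right, shrinking the interval accordingly.
#' The alternate full sequence is unchanged.
#'
#' @param allele A `contextual_allele`.
#' @return The minimal `contextual_allele`.
#' @export
trim_allele <- function(allele) {
  r <- allele$ref; a <- allele$alt
  nr <- nchar(r); na <- nchar(a)
  p <- 0L
  while (p < min(nr, na) &&
         substr(r, p + 1L, p + 1L) == substr(a, p + 1L, p + 1L)) p <- p + 1L
  s <- 0L
  while (s < min(nr, na) - p &&
         substr(r, nr - s, nr - s) == substr(a, na - s, na - s)) s <- s + 1L
  if (p == 0L && s == 0L) return(allele)
  contextual_allele(allele$ref_id, allele$start + p, allele$end - s,
                    substr(r, p + 1L, nr - s), substr(a, p + 1L, na - s))
}

is_pure_insertion <- function(a) !nzchar(a$ref) && nzchar(a$alt)
is_pure_deletion <- function(a) nzchar(a$ref) && !nzchar(a$alt)

shift_once <- function(seq, a, dir) {
  L <- nchar(seq)
  if (is_pure_deletion(a)) {
    if (dir < 0L) {
      if (a$start > 0L &&
          substr(seq, a$start, a$start) == substr(seq, a$end, a$end))
        return(contextual_allele(a$ref_id, a$start - 1L, a$end - 1L,
                                 substr(seq, a$start, a$end - 1L), ""))
    } else {
      if (a$end < L &&
          substr(seq, a$end + 1L, a$end + 1L) == substr(seq, a$start + 1L, a$start + 1L))
        return(contextual_allele(a$ref_id, a$start + 1L, a$end + 1L,
                                 substr(seq, a$start + 2L, a$end + 1L), ""))
    }
  } else if (is_pure_insertion(a)) {
    k <- nchar(a$alt)
    if (dir < 0L) {
      if (a$start > 0L &&
          substr(seq, a$start, a$start) == substr(a$alt, k, k))
        return(contextual_allele(a$ref_id, a$start - 1L, a$start - 1L, "",
                                 paste0(substr(seq, a$start, a$start),
                                        substr(a$alt, 1L, k - 1L))))
    } else {
      if (a$start < L &&
          substr(seq, a$start + 1L, a$start + 1L) == substr(a$alt, 1L, 1L))
        return(contextual_allele(a$ref_id, a$start + 1L, a$start + 1L, "",
                                 paste0(substr(a$alt, 2L, k),
                                        substr(seq, a$start + 1L, a$start + 1L))))
    }
  }
  NULL
}

shift_max <- function(db, allele, dir) {
  a <- trim_allele(allele)
  if (!(is_pure_insertion(a) || is_pure_deletion(a))) return(a)
  seq <- ref_sequence(db, a$ref_id)
  repeat {
    nxt <- shift_once(seq, a, dir)
    if (is.null(nxt)) return(a)
    a <- nxt
  }
}

#' Left-align a trimmed insertion or deletion
#'
#' Shifts the minimal representation maximally 5' without changing the
#' resulting alternate sequence. Alleles that are not pure insertions or
#' deletions after trimming cannot shift and are returned trimmed.
#'
#' @param db An `allele_refdb`.
#' @param allele A `contextual_allele`.
#' @return The left-aligned `contextual_allele`.
#' @export
left_align <- function(db, allele) shift_max(db, allele, -1L)

#' Right-align a trimmed insertion or deletion
#' @inheritParams left_align
#' @return The right-aligned `contextual_allele`.
#' @export
right_align <- function(db, allele) shift_max(db, allele, 1L)

#' Compute the normalized representations of an allele
#'
#' @param db An `allele_refdb`.
#' @param allele A `contextual_allele`.
#' @return A `normalized_allele` with fields `minimal`, `left_aligned`,
#'   `right_aligned` and `shift_range` (interbase interval of permissible
#'   anchor positions; length zero when the allele cannot shift).
#' @export
normalize_allele <- function(db, allele) {
  minimal <- trim_allele(allele)
  la <- left_align(db, minimal)
  ra <- right_align(db, minimal)
  structure(list(minimal = minimal, left_aligned = la, right_aligned = ra,
                 shift_range = c(la$start, ra$start)),
            class = "normalized_allele")
}

#' @export
print.normalized_allele <- function(x, ...) {
  cat("<normalized allele>\n")
  cat("  minimal:      ", format(x$minimal), "\n")
  cat("  left-aligned: ", format(x$left_aligned), "\n")
  cat("  right-aligned:", format(x$right_aligned), "\n")
  cat(sprintf("  shift range:   [%d,%d]\n", x$shift_range[1], x$shift_range[2]))
  invisible(x)
}

#' Enumerate all equivalent shifted representations of an allele
#'
#' Returns the left-aligned form, the right-aligned form and every
#' intermediate single-base shift, ordered 5' to 3'. Every member applies to
#' the reference to give the identical alternate sequence. Non-shiftable
#' alleles yield a list of length one.
#'
#' @param db An `allele_refdb`.
#' @param allele A `contextual_allele`.
#' @return List of `contextual_allele`s.
#' @export
enumerate_equivalents <- function(db, allele) {
  a <- left_align(db, allele)
  if (!(is_pure_insertion(a) || is_pure_deletion(a))) return(list(a))
  seq <- ref_sequence(db, a$ref_id)
  out <- list(a)
  repeat {
    nxt <- shift_once(seq, a, 1L)
    if (is.null(nxt)) break
    out[[length(out) + 1L]] <- nxt
    a <- nxt
  }
  out
}
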