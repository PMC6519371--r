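# Classed conditions so callers (and the CLI exit-code map) can dispatch on
# the kind of failure rather than on message text.

areg_abort <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "areg_error", "error", "condition"),
    c(list(message = msg, call = NULL), extra)
  )
  stop(cond)
}

#' Test whether a condition is an alleleReg error of a given class
#'
#' @param x A condition object.
#' @param class Condition class to test for (default any package error).
#' @return Logical scalar.
#' @export
is_areg_error <- function(x, class = "areg_error") {
  inherits(x, "condition") && inherits(x, class)
}

# Error classes used throughout:
#   areg_syntax          - malformed HGVS / query text
#   areg_not_supported   - recognized but unsupported construct (haplotypes)
#   areg_unknown_reference, areg_missing_reference
#   areg_reference_mismatch - stated reference allele disagrees with sequence
#   areg_ambiguous_base  - reference allele overlaps an N run
#   areg_position        - out-of-bounds / invalid position or no-op variant
#   areg_invalid_position - intron offset outside any intron
#   areg_size_limit      - allele longer than the registration cutoff
#   areg_unsupported_numbering - c. requested without a CDS annotation
#   areg_unalignable     - coordinate falls in an unaligned tail
#   areg_unprojectable   - variant overlaps an alignment edit
#   areg_no_cds          - protein consequence on a non-coding transcript
#   areg_state           - illegal registry state transition
#   areg_template_syntax - URI template rejected
#   areg_query_syntax    - malformed query
#   areg_spec            - infeasible fixture specification
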