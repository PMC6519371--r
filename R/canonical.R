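# Canonical alleles: grouping of equivalent contextual alleles across
# references under persistent CAids. The canonical key is the left-aligned
# minimal representation on the primary assembly; transcript alleles are
# projected through their alignment first (genomic left-alignment wins when
# transcript- and genome-level alignment disagree at a splice boundary).
# Alleles on references without an alignment get a reference-local key and
# are flagged non-canonicalizable.

#' Compute the canonical key of a contextual allele
#'
#' Projects the trimmed allele onto the primary assembly (strand-adjusting
#' the alleles for minus-strand transcripts), left-aligns it there, and
#' returns the resulting key. Alleles on unaligned references fall back to a
#' reference-local key.
#'
#' @param db An `allele_refdb`.
#' @param allele A validated `contextual_allele`.
#' @return A list with `key` (character), `key_allele` (the left-aligned
#'   `contextual_allele` behind the key) and `canonicalizable` (logical).
#' @export
canonicalize <- function(db, allele) {
  rec <- refdb_record(db, allele$ref_id)
  a <- trim_allele(allele)
  if (rec$kind == "genomic-primary") {
    la <- left_align(db, a)
    return(list(key = allele_key(la), key_allele = la, canonicalizable = TRUE))
  }
  if (is.null(rec$alignment)) {
    la <- left_align(db, a)
    return(list(key = paste0("local|", allele_key(la)), key_allele = la,
                canonicalizable = FALSE))
  }
  pr <- project_to_primary(db, allele$ref_id, a$start, a$end)
  alt <- if (rec$strand == "-") revcomp(a$alt) else a$alt
  gseq <- ref_sequence(db, pr$ref_id)
  ga <- contextual_allele(pr$ref_id, pr$start, pr$end,
                          substr(gseq, pr$start + 1L, pr$end), alt)
  validate_allele(db, ga)
  la <- left_align(db, ga)
  list(key = allele_key(la), key_allele = la, canonicalizable = TRUE)
}

allele_key <- function(a) {
  paste(a$ref_id, a$start, a$end, a$alt, sep = "|")
}

#' Create an empty allele registry
#'
#' The registry is an in-memory store of canonical allele records with
#' key, HGVS and external-id indices, a monotone CAid counter and an
#' append-only event log. It also hosts the link-source and link-record
#' store used by [links_for()].
#'
#' @param db An `allele_refdb` backing validation and canonicalization.
#' @return An `allele_registry` environment.
#' @export
allele_registry <- function(db) {
  reg <- new.env(parent = emptyenv())
  reg$db <- db
  reg$records <- list()           # caid -> record
  reg$key_index <- list()         # canonical key -> caid
  reg$hgvs_index <- list()        # hgvs string -> caid
  reg$ext_index <- list()         # "source|id" -> caid
  reg$counter <- 0L
  reg$events <- list()
  reg$link_sources <- list()      # source_name -> link_source
  reg$links <- list()             # "source|caid" -> named parameter list
  class(reg) <- "allele_registry"
  reg
}

#' @export
print.allele_registry <- function(x, ...) {
  st <- vapply(x$records, `[[`, "", "status")
  cat(sprintf("<allele registry> %d canonical alleles (%d active), %d link sources\n",
              length(x$records), sum(st == "active"), length(x$link_sources)))
  invisible(x)
}

log_event <- function(reg, type, ...) {
  reg$events[[length(reg$events) + 1L]] <- c(list(event = type), list(...))
  invisible(reg)
}

#' Register a contextual allele and return its CAid
#'
#' Idempotent: equivalent alleles (same canonical key) always return the same
#' CAid; new keys receive `"CA"` plus the next counter value. The allele is
#' appended to the record's member set, and its HGVS renderings and any
#' external identifier are indexed.
#'
#' @param reg An `allele_registry`.
#' @param x A `contextual_allele` or an HGVS expression string.
#' @param hgvs Optional HGVS string to index for this member (stored
#'   automatically when `x` is an expression).
#' @param external Optional `c(source, id)` external identifier to attach.
#' @return The CAid (character scalar).
#' @export
register_allele <- function(reg, x, hgvs = NULL, external = NULL) {
  if (is.character(x)) {
    if (is.null(hgvs)) hgvs <- x
    x <- parse_hgvs(reg$db, x)
  }
  validate_allele(reg$db, x)
  a <- trim_allele(x)
  cz <- canonicalize(reg$db, a)
  caid <- reg$key_index[[cz$key]]
  if (is.null(caid)) {
    reg$counter <- reg$counter + 1L
    caid <- paste0("CA", reg$counter)
    reg$records[[caid]] <- list(
      caid = caid, status = "active", replaced_by = NA_character_,
      key = cz$key, key_allele = cz$key_allele,
      canonicalizable = cz$canonicalizable,
      members = list(), external_ids = list())
    reg$key_index[[cz$key]] <- caid
    log_event(reg, "register", caid = caid, key = cz$key)
  }
  recd <- reg$records[[caid]]
  if (!any(vapply(recd$members, allele_identical, NA, b = a)))
    recd$members[[length(recd$members) + 1L]] <- a
  reg$records[[caid]] <- recd
  idx_hgvs <- character(0)
  if (!is.null(hgvs)) idx_hgvs <- hgvs
  if (cz$canonicalizable)
    idx_hgvs <- c(idx_hgvs, tryCatch(format_hgvs(reg$db, cz$key_allele, "g"),
                                     areg_error = function(e) character(0)))
  for (h in idx_hgvs) reg$hgvs_index[[h]] <- caid
  if (!is.null(external)) attach_external(reg, caid, external[1], external[2])
  caid
}

attach_external <- function(reg, caid, source, id) {
  recd <- reg$records[[caid]]
  recd$external_ids[[source]] <- unique(c(recd$external_ids[[source]], id))
  reg$records[[caid]] <- recd
  reg$ext_index[[paste0(source, "|", id)]] <- caid
  invisible(reg)
}

resolve_active <- function(reg, caid) {
  recd <- reg$records[[caid]]
  while (!is.null(recd) && recd$status == "inactive" && !is.na(recd$replaced_by))
    recd <- reg$records[[recd$replaced_by]]
  recd
}

#' Query the registry by CAid
#'
#' Inactive records are returned as themselves (they stay dereferenceable);
#' use `follow = TRUE` to resolve through `replaced_by` to the active record.
#'
#' @param reg An `allele_registry`.
#' @param caid CAid string.
#' @param follow Resolve merges to the active record.
#' @return The canonical allele record (a list), or `NULL` if never issued.
#' @export
query_caid <- function(reg, caid, follow = FALSE) {
  if (!grepl("^CA[0-9]+$", caid))
    areg_abort("areg_query_syntax", sprintf("malformed CAid: %s", caid))
  if (follow) resolve_active(reg, caid) else reg$records[[caid]]
}

#' Query the registry by HGVS expression
#' @param reg An `allele_registry`.
#' @param expr HGVS expression.
#' @return The active canonical allele record, or `NULL` when unregistered.
#' @export
query_hgvs <- function(reg, expr) {
  caid <- reg$hgvs_index[[expr]]
  if (!is.null(caid)) return(resolve_active(reg, caid))
  a <- parse_hgvs(reg$db, expr)
  cz <- canonicalize(reg$db, a)
  caid <- reg$key_index[[cz$key]]
  if (is.null(caid)) return(NULL)
  resolve_active(reg, caid)
}

#' Query the registry by external identifier
#' @param reg An `allele_registry`.
#' @param source External source name.
#' @param id Identifier within that source.
#' @return The active canonical allele record, or `NULL`.
#' @export
query_external <- function(reg, source, id) {
  caid <- reg$ext_index[[paste0(source, "|", id)]]
  if (is.null(caid)) return(NULL)
  resolve_active(reg, caid)
}

#' Query the registry by genomic region
#'
#' Returns all active records whose canonical-key interval intersects
#' `[start, end)` on the given reference (default: the primary assembly).
#' Zero-length insertion keys intersect when their anchor lies inside the
#' query interval.
#'
#' @param reg An `allele_registry`.
#' @param start,end Interbase interval.
#' @param ref_id Reference label (defaults to the primary assembly).
#' @return List of canonical allele records, ordered by CAid number.
#' @export
query_region <- function(reg, start, end, ref_id = NULL) {
  if (is.null(ref_id)) ref_id <- reg$db$primary
  if (end < start) areg_abort("areg_query_syntax", "region end before start")
  hits <- Filter(function(r) {
    if (r$status != "active") return(FALSE)
    k <- r$key_allele
    if (k$ref_id != ref_id) return(FALSE)
    if (k$start == k$end) k$start >= start && k$start <= end
    else k$start < end && k$end > start
  }, reg$records)
  hits[order(as.integer(sub("^CA", "", vapply(hits, `[[`, "", "caid"))))]
}

#' Fuzzy query: gene symbol plus partial HGVS
#'
#' Attempts the partial expression (e.g. `"c.5A>T"`) on every transcript of
#' the gene, reporting per transcript whether it validates and, if so,
#' whether the resulting allele is already registered.
#'
#' @param reg An `allele_registry`.
#' @param gene Gene symbol.
#' @param partial Partial HGVS (numbering-dot onwards, no reference prefix).
#' @return data.frame: transcript, hgvs, valid, error, registered, caid.
#' @export
query_gene_partial <- function(reg, gene, partial) {
  if (!grepl("^[cn]\\.", partial))
    areg_abort("areg_query_syntax",
               "partial expression must start with 'c.' or 'n.'")
  txs <- ref_ids(reg$db, kind = "transcript", gene = gene)
  if (!length(txs))
    return(data.frame(transcript = character(0), hgvs = character(0),
                      valid = logical(0), error = character(0),
                      registered = logical(0), caid = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(txs, function(tx) {
    expr <- paste0(tx, ":", partial)
    res <- tryCatch(parse_hgvs(reg$db, expr), areg_error = function(e) e)
    if (is_areg_error(res))
      return(data.frame(transcript = tx, hgvs = expr, valid = FALSE,
                        error = conditionMessage(res), registered = FALSE,
                        caid = NA_character_, stringsAsFactors = FALSE))
    cz <- canonicalize(reg$db, res)
    caid <- reg$key_index[[cz$key]]
    data.frame(transcript = tx, hgvs = expr, valid = TRUE, error = "",
               registered = !is.null(caid),
               caid = if (is.null(caid)) NA_character_ else caid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Merge two canonical alleles
#'
#' The loser becomes inactive with `replaced_by` pointing at the winner; its
#' members and external identifiers are appended to the winner and all
#' indices re-point. The loser's CAid remains dereferenceable.
#'
#' @param reg An `allele_registry`.
#' @param winner,loser CAids; both must be active.
#' @return The winner CAid, invisibly.
#' @export
merge_caids <- function(reg, winner, loser) {
  w <- reg$records[[winner]]; l <- reg$records[[loser]]
  if (is.null(w) || is.null(l))
    areg_abort("areg_state", "both CAids must exist")
  if (w$status != "active" || l$status != "active")
    areg_abort("areg_state", "cannot merge inactive canonical alleles")
  if (winner == loser) areg_abort("areg_state", "cannot merge a CAid with itself")
  for (m in l$members)
    if (!any(vapply(w$members, allele_identical, NA, b = m)))
      w$members[[length(w$members) + 1L]] <- m
  for (src in names(l$external_ids))
    w$external_ids[[src]] <- unique(c(w$external_ids[[src]],
                                      l$external_ids[[src]]))
  l$status <- "inactive"; l$replaced_by <- winner
  reg$records[[winner]] <- w
  reg$records[[loser]] <- l
  for (k in names(reg$key_index))
    if (reg$key_index[[k]] == loser) reg$key_index[[k]] <- winner
  for (k in names(reg$hgvs_index))
    if (reg$hgvs_index[[k]] == loser) reg$hgvs_index[[k]] <- winner
  for (k in names(reg$ext_index))
    if (reg$ext_index[[k]] == loser) reg$ext_index[[k]] <- winner
  log_event(reg, "merge", winner = winner, loser = loser)
  invisible(winner)
}

#' Split a canonical allele into two
#'
#' Operator-invoked: the old record is deactivated and each member group is
#' re-registered under a fresh CAid; `replaced_by` on the old record points
#' at the successor holding the majority of members.
#'
#' @param reg An `allele_registry`.
#' @param caid CAid to split; must be active.
#' @param groups List of two (or more) lists of member `contextual_allele`s
#'   partitioning the old membership.
#' @return Character vector of successor CAids, invisibly.
#' @export
split_caid <- function(reg, caid, groups) {
  old <- reg$records[[caid]]
  if (is.null(old) || old$status != "active")
    areg_abort("areg_state", "can only split an active canonical allele")
  if (length(groups) < 2L)
    areg_abort("areg_state", "a split needs at least two member groups")
  old$status <- "inactive"
  reg$records[[caid]] <- old
  for (k in names(reg$key_index))
    if (reg$key_index[[k]] == caid) reg$key_index[[k]] <- NULL
  succ <- vapply(groups, function(g) {
    ids <- vapply(g, function(m) register_allele(reg, m), "")
    ids[1]
  }, "")
  sizes <- vapply(groups, length, 0L)
  old <- reg$records[[caid]]
  old$replaced_by <- succ[which.max(sizes)]
  reg$records[[caid]] <- old
  log_event(reg, "split", caid = caid, successors = succ)
  invisible(succ)
}

# ---- persistence ------------------------------------------------------------

allele_to_list <- function(a)
  list(ref_id = a$ref_id, start = a$start, end = a$end, ref = a$ref, alt = a$alt)
allele_from_list <- function(l)
  contextual_allele(l$ref_id, l$start, l$end, l$ref, l$alt)

sorted_named <- function(x) if (length(x)) x[order(names(x))] else setNames(list(), character(0))

#' Serialize a registry to JSON
#'
#' The serialization is canonical (records by CAid number, indices sorted by
#' key) so that save/load/save round-trips are byte-identical.
#'
#' @param reg An `allele_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
registry_save <- function(reg, path) {
  ord <- order(as.integer(sub("^CA", "", names(reg$records))))
  recs <- lapply(reg$records[ord], function(r) {
    list(caid = r$caid, status = r$status, replaced_by = r$replaced_by,
         key = r$key, key_allele = allele_to_list(r$key_allele),
         canonicalizable = r$canonicalizable,
         members = lapply(r$members, allele_to_list),
         external_ids = sorted_named(r$external_ids))
  })
  doc <- list(counter = reg$counter,
              records = recs,
              key_index = sorted_named(reg$key_index),
              hgvs_index = sorted_named(reg$hgvs_index),
              ext_index = sorted_named(reg$ext_index),
              link_sources = lapply(sorted_named(reg$link_sources), unclass),
              links = sorted_named(reg$links),
              events = reg$events)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       na = "null", digits = NA, pretty = FALSE)
  invisible(path)
}

#' Load a registry serialized with [registry_save()]
#' @param path JSON path.
#' @param db The `allele_refdb` the registry was built against.
#' @return An `allele_registry`.
#' @export
registry_load <- function(path, db) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- allele_registry(db)
  reg$counter <- as.integer(doc$counter)
  reg$records <- lapply(doc$records, function(r) {
    list(caid = r$caid, status = r$status,
         replaced_by = if (is.null(r$replaced_by)) NA_character_ else r$replaced_by,
         key = r$key, key_allele = allele_from_list(r$key_allele),
         canonicalizable = isTRUE(r$canonicalizable),
         members = lapply(r$members, allele_from_list),
         external_ids = lapply(r$external_ids, function(v) unlist(v)))
  })
  names(reg$records) <- vapply(doc$records, `[[`, "", "caid")
  reg$key_index <- lapply(doc$key_index, identity)
  reg$hgvs_index <- lapply(doc$hgvs_index, identity)
  reg$ext_index <- lapply(doc$ext_index, identity)
  reg$link_sources <- lapply(doc$link_sources, function(s) {
    structure(list(source_name = s$source_name, api_template = s$api_template,
                   ui_template = if (is.null(s$ui_template)) NA_character_ else s$ui_template,
                   parameter_names = as.character(unlist(s$parameter_names))),
              class = "link_source")
  })
  reg$links <- lapply(doc$links, function(v) lapply(v, identity))
  reg$events <- doc$events
  reg
}

#' JSON document for a canonical allele record
#'
#' Flat-keyed, stable-ordered document carrying the CAid, an `@id` URI, the
#' status, the canonical key allele, all members with their HGVS renderings,
#' external identifiers and expanded links.
#'
#' @param reg An `allele_registry`.
#' @param caid CAid string.
#' @param uri_base Prefix for the `@id` field.
#' @return A list suitable for `jsonlite::toJSON(auto_unbox = TRUE)`.
#' @export
allele_document <- function(reg, caid, uri_base = "allele/") {
  r <- reg$records[[caid]]
  if (is.null(r)) return(NULL)
  members <- lapply(r$members, function(m) {
    hg <- tryCatch(format_hgvs(reg$db, m), areg_error = function(e) NA_character_)
    c(allele_to_list(m), list(hgvs = hg))
  })
  lk <- links_for(reg, caid)
  list(`@id` = paste0(uri_base, caid), caid = r$caid, status = r$status,
       replaced_by = r$replaced_by, canonical_key = r$key,
       key_allele = allele_to_list(r$key_allele),
       canonicalizable = r$canonicalizable,
       members = members, external_ids = sorted_named(r$external_ids),
       links = lk)
}

#' Write registered alleles as an annotated VCF
#'
#' Emits one record per allele with the CAid in the INFO field (`CAID=` key).
#' Insertions and deletions are written with the VCF anchor-base convention.
#'
#' @param reg An `allele_registry`.
#' @param alleles List of `contextual_allele`s on genomic references.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registered_vcf <- function(reg, alleles, path) {
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=CAID,Number=1,Type=String,Description=\"Canonical allele identifier\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
  for (a in alleles) {
    cz <- canonicalize(reg$db, a)
    caid <- reg$key_index[[cz$key]]
    info <- if (is.null(caid)) "." else paste0("CAID=", caid)
    k <- cz$key_allele
    seq <- ref_sequence(reg$db, k$ref_id)
    if (nzchar(k$ref) && nzchar(k$alt) && nchar(k$ref) == 1L && nchar(k$alt) == 1L) {
      pos <- k$start + 1L; ref <- k$ref; alt <- k$alt
    } else {
      # anchor base immediately 5' of the change
      anchor <- substr(seq, k$start, k$start)
      pos <- k$start; ref <- paste0(anchor, k$ref); alt <- paste0(anchor, k$alt)
    }
    lines <- c(lines, paste(k$ref_id, pos, ".", ref, alt, ".", ".", info,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
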