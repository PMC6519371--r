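# Desk-scale mining over the registry: deduplication of variant streams by
# canonicalization, and discordance mining among nucleotide variants that
# produce the same alternate protein sequence — discordant pathogenicity
# assertions, and allele-frequency spreads crossing the rare/common
# thresholds.

CLASSIFICATIONS <- c("benign", "likely-benign", "uncertain",
                     "likely-pathogenic", "pathogenic")
COLLAPSED <- c(benign = "benign", `likely-benign` = "benign",
               uncertain = "uncertain",
               `likely-pathogenic` = "pathogenic", pathogenic = "pathogenic")
SEVERITY <- c(benign = 1L, uncertain = 2L, pathogenic = 3L)

#' Find duplicate variants in a stream by canonicalization
#'
#' Variants mapping to the same canonical key form one duplicate group.
#' Unreadable or invalid records are skipped (and counted), never fatal.
#' The result is invariant under permutation of the input.
#'
#' @param db An `allele_refdb` (an `allele_registry` is also accepted).
#' @param x A VCF path, a character vector of HGVS expressions, or a list of
#'   `contextual_allele`s.
#' @return List: `n_input`, `n_processed`, `n_skipped`, `n_distinct`,
#'   `n_duplicates` (= processed - distinct), `groups` (per duplicated key,
#'   the input indices mapping to it, keys sorted), `skipped` (indices).
#' @export
find_duplicates <- function(db, x) {
  if (inherits(db, "allele_registry")) db <- db$db
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      grepl("\\.vcf$", x)) {
    parsed <- read_vcf_alleles(db, x)
    alleles <- parsed$alleles
  } else if (is.character(x)) {
    alleles <- lapply(x, function(e)
      tryCatch(parse_hgvs(db, e), areg_error = function(err) NULL))
  } else {
    alleles <- lapply(x, function(a)
      tryCatch({ validate_allele(db, a); trim_allele(a) },
               areg_error = function(err) NULL))
  }
  n <- length(alleles)
  keys <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.null(alleles[[i]])) next
    keys[i] <- tryCatch(canonicalize(db, alleles[[i]])$key,
                        areg_error = function(err) NA_character_)
  }
  ok <- !is.na(keys)
  grp <- split(which(ok), keys[ok])
  grp <- grp[order(names(grp))]
  dup_grp <- grp[lengths(grp) >= 2L]
  list(n_input = n, n_processed = sum(ok), n_skipped = sum(!ok),
       n_distinct = length(grp),
       n_duplicates = sum(ok) - length(grp),
       groups = dup_grp, skipped = which(!ok))
}

# Resolve an assertion/frequency table (hgvs + value columns) to canonical
# keys and protein effects. Returns kept rows with key/protein columns and
# the excluded rows with reasons.
resolve_protein_table <- function(db, tab) {
  n <- nrow(tab)
  key <- rep(NA_character_, n); prot <- rep(NA_character_, n)
  why <- rep("", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      a <- parse_hgvs(db, tab$hgvs[i])
      k <- canonicalize(db, a)$key
      pe <- protein_consequence(db, a)
      if (is.na(pe$alt_protein)) areg_abort("areg_no_cds", "no computable protein effect")
      list(key = k, prot = pe$alt_protein)
    }, areg_error = function(e) e)
    if (is_areg_error(res)) why[i] <- conditionMessage(res)
    else { key[i] <- res$key; prot[i] <- res$prot }
  }
  tab$key <- key; tab$protein <- prot
  list(kept = tab[!is.na(key), , drop = FALSE],
       excluded = cbind(tab[is.na(key), , drop = FALSE],
                        reason = why[is.na(key)]))
}

#' Pairwise assertion discordance among same-protein-effect variants
#'
#' Five-level classifications are collapsed to three (likely-benign with
#' benign, likely-pathogenic with pathogenic). For every unordered pair of
#' distinct nucleotide variants sharing an identical alternate protein
#' sequence, the cell (more severe, less severe) of a 3x3 lower-triangular
#' matrix is incremented. Off-diagonal pairs are discordant. Variants
#' carrying several assertions keep the most severe one.
#'
#' @param db An `allele_refdb` (or `allele_registry`).
#' @param assertions data.frame with columns `hgvs` and `classification`
#'   (one of benign, likely-benign, uncertain, likely-pathogenic,
#'   pathogenic).
#' @return List: `matrix` (3x3 lower-triangular pair counts), `pairs`
#'   (data.frame of all qualifying pairs), `discordant` (the off-diagonal
#'   subset), `groups` (group-level report), `variant_tally` (per-variant
#'   discordance involvement), `excluded`.
#' @export
discordance_matrix <- function(db, assertions) {
  if (inherits(db, "allele_registry")) db <- db$db
  bad <- setdiff(assertions$classification, CLASSIFICATIONS)
  if (length(bad))
    areg_abort("areg_query_syntax",
               sprintf("unknown classification(s): %s", paste(bad, collapse = ", ")))
  res <- resolve_protein_table(db, assertions)
  kept <- res$kept
  lv <- c("benign", "uncertain", "pathogenic")
  mat <- matrix(0L, 3, 3, dimnames = list(lv, lv))
  pairs <- list()
  if (nrow(kept)) {
    kept$collapsed <- unname(COLLAPSED[kept$classification])
    # one classification per distinct nucleotide variant: most severe wins
    agg <- do.call(rbind, lapply(split(kept, kept$key), function(d) {
      d[which.max(SEVERITY[d$collapsed]), c("hgvs", "key", "protein", "collapsed")]
    }))
    agg <- agg[order(agg$key), , drop = FALSE]
    for (g in split(agg, agg$protein)) {
      if (nrow(g) < 2L) next
      for (i in seq_len(nrow(g) - 1L)) for (j in seq((i + 1L), nrow(g))) {
        ci <- g$collapsed[i]; cj <- g$collapsed[j]
        hi <- if (SEVERITY[ci] >= SEVERITY[cj]) ci else cj
        lo <- if (SEVERITY[ci] >= SEVERITY[cj]) cj else ci
        mat[hi, lo] <- mat[hi, lo] + 1L
        pairs[[length(pairs) + 1L]] <- data.frame(
          hgvs_a = g$hgvs[i], class_a = ci, hgvs_b = g$hgvs[j], class_b = cj,
          discordant = ci != cj, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(hgvs_a = character(0), class_a = character(0),
               hgvs_b = character(0), class_b = character(0),
               discordant = logical(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$hgvs_a, pairs$hgvs_b), , drop = FALSE]
  rownames(pairs) <- NULL
  disc <- pairs[pairs$discordant, , drop = FALSE]
  groups <- if (nrow(kept)) {
    agg2 <- do.call(rbind, lapply(split(kept, kept$key), function(d)
      d[which.max(SEVERITY[unname(COLLAPSED[d$classification])]), , drop = FALSE]))
    gl <- lapply(split(agg2, agg2$protein), function(d)
      list(n_variants = nrow(d),
           classes = sort(unique(unname(COLLAPSED[d$classification]))),
           hgvs = sort(d$hgvs)))
    gl[vapply(gl, function(g) g$n_variants >= 2L, NA)]
  } else list()
  tally <- sort(table(c(disc$hgvs_a, disc$hgvs_b)), decreasing = TRUE)
  list(matrix = mat, pairs = pairs, discordant = disc, groups = groups,
       variant_tally = tally, excluded = res$excluded)
}

#' Frequency discordance among same-protein-effect variants
#'
#' Among groups of variants producing the same alternate protein sequence,
#' report those whose lowest allele frequency is below `lo` and highest
#' above `hi` (defaults: 1% and 5%).
#'
#' @param db An `allele_refdb` (or `allele_registry`).
#' @param frequencies data.frame with columns `hgvs` and `af` in \[0, 1\].
#' @param lo,hi Rare/common thresholds.
#' @return List: `groups` (discordant groups with member hgvs and
#'   frequencies), `n_groups_tested`, `excluded`.
#' @export
frequency_discordance <- function(db, frequencies, lo = 0.01, hi = 0.05) {
  if (inherits(db, "allele_registry")) db <- db$db
  if (any(is.na(frequencies$af)) || any(frequencies$af < 0 | frequencies$af > 1))
    areg_abort("areg_query_syntax", "allele frequencies must lie in [0, 1]")
  res <- resolve_protein_table(db, frequencies)
  kept <- res$kept
  out <- list(); tested <- 0L
  if (nrow(kept)) {
    for (p in sort(unique(kept$protein))) {
      g <- kept[kept$protein == p, , drop = FALSE]
      if (length(unique(g$key)) < 2L) next
      tested <- tested + 1L
      if (min(g$af) < lo && max(g$af) > hi) {
        o <- order(g$hgvs)
        out[[length(out) + 1L]] <- list(protein_group = p,
                                        hgvs = g$hgvs[o], af = g$af[o],
                                        min_af = min(g$af), max_af = max(g$af))
      }
    }
  }
  list(groups = out, n_groups_tested = tested, excluded = res$excluded)
}
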