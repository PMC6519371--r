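# Link layering: external sources register RFC 6570 URI templates and attach
# per-CAid parameter values; links are expanded on demand. Only level-1
# simple string expansion ({var}) is accepted — every template the registry
# needs is a plain substitution — and values are percent-encoded over their
# UTF-8 bytes, keeping only unreserved characters.

TEMPLATE_VAR_RE <- "\\{([A-Za-z_][A-Za-z0-9_]*)\\}"

template_vars <- function(template) {
  m <- gregexpr(TEMPLATE_VAR_RE, template)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(template, list(m))[[1]]
  substr(toks, 2L, nchar(toks) - 1L)
}

check_template <- function(template) {
  stripped <- gsub(TEMPLATE_VAR_RE, "", template)
  if (grepl("[{}]", stripped))
    areg_abort("areg_template_syntax",
               sprintf("only level-1 {var} expressions are supported: %s",
                       template))
  invisible(template)
}

#' Percent-encode a value for URI template expansion
#'
#' RFC 6570 simple string expansion: unreserved characters
#' (`A-Z a-z 0-9 - . _ ~`) pass through; every other UTF-8 byte becomes
#' `%XX`.
#'
#' @param x Character scalar.
#' @return Encoded character scalar.
#' @export
pct_encode <- function(x) {
  bytes <- charToRaw(enc2utf8(as.character(x)))
  v <- as.integer(bytes)
  ok <- (v >= 0x30 & v <= 0x39) | (v >= 0x41 & v <= 0x5A) |
    (v >= 0x61 & v <= 0x7A) | v %in% c(0x2DL, 0x2EL, 0x5FL, 0x7EL)
  out <- character(length(v))
  if (any(ok)) out[ok] <- vapply(bytes[ok], rawToChar, "")
  if (any(!ok)) out[!ok] <- paste0("%", toupper(as.character(bytes[!ok])))
  paste(out, collapse = "")
}

#' Expand a level-1 URI template
#'
#' @param template Template text with `{var}` placeholders.
#' @param values Named list/vector of variable values.
#' @return The expanded URI. Missing variables raise an error.
#' @export
expand_uri_template <- function(template, values) {
  check_template(template)
  vars <- template_vars(template)
  out <- template
  for (v in vars) {
    val <- values[[v]]
    if (is.null(val) || is.na(val))
      areg_abort("areg_template_syntax",
                 sprintf("no value supplied for template variable {%s}", v))
    out <- gsub(paste0("{", v, "}"), pct_encode(val), out, fixed = TRUE)
  }
  out
}

#' Define a link source
#'
#' @param source_name Unique source label.
#' @param api_template RFC 6570 level-1 template for machine-readable
#'   content.
#' @param ui_template Optional template for human-readable content.
#' @param parameter_names Parameters the source will attach per CAid; every
#'   template variable must be `caid` or one of these.
#' @return A `link_source`.
#' @export
link_source <- function(source_name, api_template, ui_template = NULL,
                        parameter_names = character()) {
  check_template(api_template)
  if (!is.null(ui_template)) check_template(ui_template)
  allowed <- c("caid", parameter_names)
  used <- unique(c(template_vars(api_template),
                   if (is.null(ui_template)) character(0)
                   else template_vars(ui_template)))
  bad <- setdiff(used, allowed)
  if (length(bad))
    areg_abort("areg_template_syntax",
               sprintf("template variable(s) not declared: %s",
                       paste(bad, collapse = ", ")))
  structure(list(source_name = source_name, api_template = api_template,
                 ui_template = if (is.null(ui_template)) NA_character_
                               else ui_template,
                 parameter_names = as.character(parameter_names)),
            class = "link_source")
}

#' Register a link source with the registry
#'
#' Idempotent by source name: re-registering identical content is a no-op;
#' differing content replaces the stored source.
#'
#' @param reg An `allele_registry`.
#' @param source A [link_source()].
#' @return The stored source, invisibly.
#' @export
register_link_source <- function(reg, source) {
  stopifnot(inherits(source, "link_source"))
  old <- reg$link_sources[[source$source_name]]
  if (!identical(unclass(old), unclass(source))) {
    reg$link_sources[[source$source_name]] <- source
    log_event(reg, "link_source", source = source$source_name)
  }
  invisible(source)
}

#' Attach link records to CAids (bulk upsert)
#'
#' Each record binds parameter values for one CAid under one source.
#' Records naming a CAid that was never issued are rejected individually;
#' the batch continues. Re-uploading identical records changes nothing and
#' counts zero.
#'
#' @param reg An `allele_registry`.
#' @param source_name A registered link source.
#' @param records A data.frame with a `caid` column plus one column per
#'   declared parameter, or a list of lists with those fields.
#' @return List: `stored` (count of new or changed records), `rejected`
#'   (data.frame of refused records with reasons).
#' @export
put_links <- function(reg, source_name, records) {
  src <- reg$link_sources[[source_name]]
  if (is.null(src))
    areg_abort("areg_state", sprintf("unknown link source: %s", source_name))
  if (is.data.frame(records))
    records <- lapply(seq_len(nrow(records)),
                      function(i) as.list(records[i, , drop = FALSE]))
  stored <- 0L
  rej_caid <- character(0); rej_why <- character(0)
  for (r in records) {
    caid <- as.character(r$caid)
    if (is.null(reg$records[[caid]])) {
      rej_caid <- c(rej_caid, caid)
      rej_why <- c(rej_why, "unknown CAid")
      next
    }
    params <- r[setdiff(names(r), "caid")]
    extra <- setdiff(names(params), src$parameter_names)
    if (length(extra)) {
      rej_caid <- c(rej_caid, caid)
      rej_why <- c(rej_why, paste0("undeclared parameter(s): ",
                                   paste(extra, collapse = ",")))
      next
    }
    params <- lapply(params, as.character)
    key <- paste0(source_name, "|", caid)
    if (!identical(reg$links[[key]], params)) {
      reg$links[[key]] <- params
      stored <- stored + 1L
    }
  }
  list(stored = stored,
       rejected = data.frame(caid = rej_caid, reason = rej_why,
                             stringsAsFactors = FALSE))
}

#' Expand all links registered for a CAid
#'
#' Link records survive merges: the queried CAid is resolved through
#' `replaced_by`, and records attached to any CAid in the merged family are
#' collected. Sources whose templates need a parameter that was never
#' attached are skipped with a warning rather than failing.
#'
#' @param reg An `allele_registry`.
#' @param caid CAid string.
#' @return data.frame: source, api_uri, ui_uri (NA when no UI template).
#' @export
links_for <- function(reg, caid) {
  empty <- data.frame(source = character(0), api_uri = character(0),
                      ui_uri = character(0), stringsAsFactors = FALSE)
  active <- resolve_active(reg, caid)
  if (is.null(active)) return(empty)
  family <- names(Filter(function(r) {
    ra <- resolve_active(reg, r$caid)
    !is.null(ra) && ra$caid == active$caid
  }, reg$records))
  out <- empty
  for (nm in sort(names(reg$link_sources))) {
    src <- reg$link_sources[[nm]]
    params <- NULL; found <- FALSE
    for (fc in family) {
      rec <- reg$links[[paste0(nm, "|", fc)]]
      if (!is.null(rec)) { params <- rec; found <- TRUE; break }
    }
    # a PUT record (possibly with no parameters, the caid-only pattern)
    # marks that the source has content for this allele
    if (!found) next
    vals <- c(list(caid = active$caid), params)
    uri <- tryCatch(expand_uri_template(src$api_template, vals),
                    areg_error = function(e) e)
    if (is_areg_error(uri)) {
      warning(sprintf("link for %s via %s omitted: %s", caid, nm,
                      conditionMessage(uri)), call. = FALSE)
      next
    }
    ui <- NA_character_
    if (!is.na(src$ui_template)) {
      ui <- tryCatch(expand_uri_template(src$ui_template, vals),
                     areg_error = function(e) e)
      if (is_areg_error(ui)) {
        warning(sprintf("UI link for %s via %s omitted: %s", caid, nm,
                        conditionMessage(ui)), call. = FALSE)
        ui <- NA_character_
      }
    }
    out <- rbind(out, data.frame(source = nm, api_uri = uri, ui_uri = ui,
                                 stringsAsFactors = FALSE))
  }
  out
}
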