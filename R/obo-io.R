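# OBO 1.2 flat-file reader/writer for the dialect used by the Xenopus
# Anatomy Ontology: [Term]/[Typedef] stanzas, tag: value lines, trailing
# "!" comments, \" and \! escapes. OWL-specific constructs are rejected.

#' The six XAO relation types
#'
#' Relation vocabulary of the ontology: `is_a`, `part_of` and
#' `develops_from` connect anatomical entities (`develops_from` points from
#' a structure to its precursor, `part_of` from part to whole);
#' `starts_during` and `ends_during` anchor an anatomical entity to a
#' developmental stage; `preceded_by` orders consecutive stages.
#'
#' @return Character vector of the six relation names.
#' @export
xao_relation_types <- function() {
  c("is_a", "part_of", "develops_from",
    "starts_during", "ends_during", "preceded_by")
}

#' @rdname xao_relation_types
#' @export
xao_synonym_scopes <- function() c("EXACT", "BROAD", "NARROW", "RELATED")

# header tags accepted before the first stanza
.obo_header_tags <- c(
  "format-version", "data-version", "date", "saved-by", "auto-generated-by",
  "default-namespace", "namespace", "ontology", "remark", "subsetdef",
  "synonymtypedef", "import", "idspace", "property_value",
  "treat-xrefs-as-equivalent", "treat-xrefs-as-genus-differentia",
  "treat-xrefs-as-is_a", "default-relationship-id-prefix"
)

# term-stanza tags parsed into structured fields; everything else is kept
# as an opaque line so the file round-trips
.obo_term_tags <- c("id", "name", "namespace", "def", "synonym", "xref",
                    "is_a", "relationship", "is_obsolete")

#' Create an empty term stanza
#'
#' @param id Term identifier (e.g. `"XAO:0000010"`).
#' @param name Term label.
#' @param namespace OBO namespace, `NA` to inherit the default.
#' @param def Definition text (`NA` if absent).
#' @param def_xrefs Character vector of definition-source xrefs (the
#'   bracketed list on the `def` line), kept separate from term-level xrefs.
#' @param synonyms Data frame with columns `label`, `scope`.
#' @param xrefs Character vector of term-level cross-references.
#' @param is_a Character vector of parent term ids.
#' @param relationships Data frame with columns `relation`, `target`.
#' @param is_obsolete Logical flag.
#' @param other Character vector of retained opaque `tag: value` lines.
#' @return An object of class `obo_term`.
#' @export
obo_term <- function(id, name = NA_character_, namespace = NA_character_,
                     def = NA_character_, def_xrefs = character(),
                     synonyms = empty_synonyms(), xrefs = character(),
                     is_a = character(), relationships = empty_relationships(),
                     is_obsolete = FALSE, other = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(
    list(id = id, name = name, namespace = namespace,
         def = def, def_xrefs = def_xrefs, synonyms = synonyms,
         xrefs = xrefs, is_a = is_a, relationships = relationships,
         is_obsolete = isTRUE(is_obsolete), other = other),
    class = "obo_term")
}

#' @rdname obo_term
#' @export
empty_synonyms <- function() {
  data.frame(label = character(), scope = character(),
             stringsAsFactors = FALSE)
}

#' @rdname obo_term
#' @export
empty_relationships <- function() {
  data.frame(relation = character(), target = character(),
             stringsAsFactors = FALSE)
}

#' Construct an ontology document
#'
#' An `obo_document` is a faithful in-memory image of an OBO flat file:
#' the header (ordered `tag: value` lines) plus the ordered term and
#' typedef stanzas.
#'
#' @param header Character vector of raw header lines in file order.
#' @param terms Named list of [obo_term()] stanzas (names are term ids,
#'   file order preserved).
#' @param typedefs Named list of typedef stanzas, each a list with at least
#'   `id` and `other` (raw retained lines).
#' @return An object of class `obo_document`.
#' @export
obo_document <- function(header = "format-version: 1.2",
                         terms = list(), typedefs = list()) {
  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[duplicated(ids)][1], call. = FALSE)
  names(terms) <- ids
  if (length(typedefs))
    names(typedefs) <- vapply(typedefs, function(t) t$id, character(1))
  structure(list(header = header, terms = terms, typedefs = typedefs),
            class = "obo_document")
}

#' @export
print.obo_document <- function(x, ...) {
  cat("OBO document:", length(x$terms), "term stanzas,",
      length(x$typedefs), "typedefs\n")
  invisible(x)
}

#' @export
print.obo_term <- function(x, ...) {
  cat("[Term] ", x$id, if (!is.na(x$name)) paste0(" (", x$name, ")"),
      if (x$is_obsolete) " OBSOLETE", "\n", sep = "")
  invisible(x)
}

# strip a trailing unescaped "!" comment; honors backslash escapes
.strip_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "\\") {
      i <- i + 2L
    } else if (chars[i] == "!") {
      return(trimws(paste(chars[seq_len(i - 1L)], collapse = "")))
    } else {
      i <- i + 1L
    }
  }
  trimws(line)
}

.obo_unescape <- function(x) {
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  x <- gsub("\\!", "!", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

.obo_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("!", "\\!", x, fixed = TRUE)
}

# parse `"quoted text" rest` -> list(text=, rest=); escapes honored
.parse_quoted <- function(value, lineno) {
  if (!startsWith(value, "\""))
    stop("line ", lineno, ": expected quoted string in: ", value,
         call. = FALSE)
  chars <- strsplit(value, "", fixed = TRUE)[[1]]
  i <- 2L
  out <- character(0)
  n <- length(chars)
  while (i <= n) {
    if (chars[i] == "\\" && i < n) {
      out <- c(out, chars[i], chars[i + 1L])
      i <- i + 2L
    } else if (chars[i] == "\"") {
      return(list(text = .obo_unescape(paste(out, collapse = "")),
                  rest = trimws(paste(chars[seq.int(i + 1L, length.out = n - i)],
                                      collapse = ""))))
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  stop("line ", lineno, ": unterminated quoted string", call. = FALSE)
}

# parse a bracketed xref list "[A:1, B:2]" -> character vector
.parse_bracket_list <- function(rest) {
  if (!nzchar(rest) || !startsWith(rest, "[")) return(character())
  inner <- sub("^\\[", "", sub("\\].*$", "", rest))
  if (!nzchar(trimws(inner))) return(character())
  trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
}

#' Parse an OBO 1.2 flat file
#'
#' Reads the pragmatic OBO 1.2 subset used by XAO releases. Structured tags
#' (`id`, `name`, `namespace`, `def`, `synonym`, `xref`, `is_a`,
#' `relationship`, `is_obsolete`) are parsed into [obo_term()] fields;
#' any other tag inside a stanza is retained opaquely so that
#' `parse_obo(write_obo(d))` reproduces `d`. Text after an unescaped
#' `!` on a value line is discarded (OBO trailing comments); lines starting
#' with `!` are ignored.
#'
#' @param x Path to an OBO file, or a character vector of lines (anything
#'   of length > 1, or containing a newline, is treated as content).
#' @return An [obo_document()].
#' @examples
#' doc <- parse_obo(c("format-version: 1.2", "", "[Term]",
#'                    "id: XAO:0000010", "name: brain"))
#' doc$terms[["XAO:0000010"]]$name
#' @export
parse_obo <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }

  header <- character()
  terms <- list()
  typedefs <- list()
  state <- "header"      # header | term | typedef | skip
  cur <- NULL

  flush_stanza <- function() {
    if (is.null(cur)) return()
    if (state == "term") {
      if (is.na(cur$id) || !nzchar(cur$id))
        stop("term stanza without id (near line ", cur$line, ")",
             call. = FALSE)
      if (!is.null(terms[[cur$id]]))
        stop("duplicate term id: ", cur$id, call. = FALSE)
      terms[[cur$id]] <<- obo_term(
        cur$id, cur$name, cur$namespace, cur$def, cur$def_xrefs,
        data.frame(label = cur$syn_label, scope = cur$syn_scope,
                   stringsAsFactors = FALSE),
        cur$xrefs, cur$is_a,
        data.frame(relation = cur$rel_relation, target = cur$rel_target,
                   stringsAsFactors = FALSE),
        cur$is_obsolete, cur$other)
    } else if (state == "typedef") {
      if (is.na(cur$id))
        stop("typedef stanza without id (near line ", cur$line, ")",
             call. = FALSE)
      typedefs[[cur$id]] <<- list(id = cur$id, name = cur$name,
                                  other = cur$other)
    }
  }

  new_stanza <- function(lineno) {
    list(id = NA_character_, name = NA_character_, namespace = NA_character_,
         def = NA_character_, def_xrefs = character(),
         syn_label = character(), syn_scope = character(),
         xrefs = character(), is_a = character(),
         rel_relation = character(), rel_target = character(),
         is_obsolete = FALSE, other = character(), line = lineno)
  }

  for (i in seq_along(lines)) {
    raw <- lines[i]
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "!")) next

    if (startsWith(line, "[")) {
      flush_stanza()
      hdr <- line
      if (hdr == "[Term]") {
        state <- "term"; cur <- new_stanza(i)
      } else if (hdr == "[Typedef]") {
        state <- "typedef"; cur <- new_stanza(i)
      } else {
        stop("line ", i, ": unreadable stanza header: ", hdr, call. = FALSE)
      }
      next
    }

    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0)
      stop("line ", i, ": not a tag: value line: ", line, call. = FALSE)
    tag <- trimws(substr(line, 1L, m - 1L))
    value <- .strip_comment(trimws(substr(line, m + 1L, nchar(line))))

    if (state == "header") {
      if (!(tag %in% .obo_header_tags))
        stop("line ", i, ": tag '", tag,
             "' before any stanza is not a header tag", call. = FALSE)
      header <- c(header, paste0(tag, ": ", value))
      next
    }

    if (state == "typedef") {
      if (tag == "id") cur$id <- value
      else if (tag == "name") cur$name <- value
      else cur$other <- c(cur$other, paste0(tag, ": ", value))
      next
    }

    # term stanza
    switch(tag,
      id = { cur$id <- value },
      name = { cur$name <- .obo_unescape(value) },
      namespace = { cur$namespace <- value },
      def = {
        q <- .parse_quoted(value, i)
        cur$def <- q$text
        cur$def_xrefs <- .parse_bracket_list(q$rest)
      },
      synonym = {
        q <- .parse_quoted(value, i)
        scope_tok <- strsplit(q$rest, "[ \t\\[]")[[1]]
        scope_tok <- scope_tok[nzchar(scope_tok)]
        scope <- if (length(scope_tok)) scope_tok[1] else "RELATED"
        if (!(scope %in% xao_synonym_scopes()))
          stop("line ", i, ": invalid synonym scope: ", scope, call. = FALSE)
        cur$syn_label <- c(cur$syn_label, q$text)
        cur$syn_scope <- c(cur$syn_scope, scope)
      },
      xref = {
        # drop an optional trailing quoted description
        cur$xrefs <- c(cur$xrefs, trimws(sub("\\s+\".*$", "", value)))
      },
      is_a = { cur$is_a <- c(cur$is_a, trimws(value)) },
      relationship = {
        parts <- strsplit(trimws(value), "[ \t]+")[[1]]
        if (length(parts) < 2L)
          stop("line ", i, ": malformed relationship line: ", value,
               call. = FALSE)
        cur$rel_relation <- c(cur$rel_relation, parts[1])
        cur$rel_target <- c(cur$rel_target, parts[2])
      },
      is_obsolete = { cur$is_obsolete <- identical(tolower(value), "true") },
      { cur$other <- c(cur$other, paste0(tag, ": ", value)) }
    )
  }
  flush_stanza()

  doc <- obo_document(header = header, terms = terms, typedefs = typedefs)

  # relation names must be among the six or declared as typedefs
  used <- unique(unlist(lapply(doc$terms, function(t) t$relationships$relation),
                        use.names = FALSE))
  undeclared <- setdiff(used, c(xao_relation_types(), names(doc$typedefs)))
  if (length(undeclared))
    stop("undeclared relation type(s): ", paste(undeclared, collapse = ", "),
         call. = FALSE)
  doc
}

#' Serialize an ontology document to OBO text
#'
#' Writes stanzas in document order with a deterministic canonical tag
#' order (`id`, `name`, `namespace`, `def`, `synonym`, `xref`, `is_a`,
#' `relationship`, `is_obsolete`, retained lines), so identical documents
#' always produce byte-identical text and `parse_obo(write_obo(d))`
#' reproduces `d`.
#'
#' @param doc An [obo_document()].
#' @param path Optional file path; when given, text is written there with a
#'   trailing newline and returned invisibly.
#' @return Character scalar of OBO text.
#' @export
write_obo <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "obo_document"))
  ids <- vapply(doc$terms, function(t) t$id, character(1))
  if (any(is.na(ids) | !nzchar(ids)))
    stop("stanza missing id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[duplicated(ids)][1], call. = FALSE)

  out <- doc$header
  for (t in doc$terms) {
    s <- c("", "[Term]", paste0("id: ", t$id))
    if (!is.na(t$name)) s <- c(s, paste0("name: ", .obo_escape(t$name)))
    if (!is.na(t$namespace)) s <- c(s, paste0("namespace: ", t$namespace))
    if (!is.na(t$def)) {
      xr <- paste0("[", paste(t$def_xrefs, collapse = ", "), "]")
      s <- c(s, paste0("def: \"", .obo_escape(t$def), "\" ", xr))
    }
    if (nrow(t$synonyms))
      s <- c(s, paste0("synonym: \"", .obo_escape(t$synonyms$label), "\" ",
                       t$synonyms$scope, " []"))
    if (length(t$xrefs)) s <- c(s, paste0("xref: ", t$xrefs))
    if (length(t$is_a)) s <- c(s, paste0("is_a: ", t$is_a))
    if (nrow(t$relationships))
      s <- c(s, paste0("relationship: ", t$relationships$relation, " ",
                       t$relationships$target))
    if (t$is_obsolete) s <- c(s, "is_obsolete: true")
    if (length(t$other)) s <- c(s, t$other)
    out <- c(out, s)
  }
  for (td in doc$typedefs) {
    s <- c("", "[Typedef]", paste0("id: ", td$id))
    if (!is.null(td$name) && !is.na(td$name))
      s <- c(s, paste0("name: ", td$name))
    if (length(td$other)) s <- c(s, td$other)
    out <- c(out, s)
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' Test two ontology documents for semantic equality
#'
#' Stanza-by-stanza comparison of ids, names, namespaces, definitions with
#' their source xrefs, synonyms, xrefs, relations, obsolescence flags and
#' retained opaque lines, plus header equality. Stanza order matters
#' (documents are ordered collections).
#'
#' @param a,b Two [obo_document()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
obo_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), check.attributes = TRUE))
}
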