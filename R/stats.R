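# Release content summaries (the counts a release table reports) and
# inter-release diffs keyed by term id, edge triple, synonym and xref.

#' Summarize ontology content
#'
#' Counts over non-obsolete stanzas: total terms, the partition into
#' anatomical entities and developmental stages (stage terms are those in
#' the stage series), definitions, synonyms, relationship types in use,
#' asserted relationship lines per relation (an `is_a` line counts toward
#' `is_a`; inferred closure edges are never counted) and term-level
#' cross-references (definition-source xrefs are excluded).
#'
#' @param graph An `xao_graph`.
#' @param series A `stage_series`; built from `graph` when omitted, with a
#'   stage count of 0 if no stage terms exist.
#' @return A list of class `xao_stats` with fields `total_terms`,
#'   `anatomical_entities`, `developmental_stages`, `definitions`,
#'   `synonyms`, `relationship_types`, `relationships_total`,
#'   `per_relation` (named integer vector over the six relations) and
#'   `xrefs`.
#' @examples
#' g <- build_graph(figure2_fixture())
#' summarize_ontology(g)$per_relation
#' @export
summarize_ontology <- function(graph, series = NULL) {
  stopifnot(inherits(graph, "xao_graph"))
  if (is.null(series))
    series <- tryCatch(build_stage_series(graph), error = function(e) NULL)
  stage_ids <- if (is.null(series)) character(0) else series$ids

  terms <- graph$terms
  e <- graph$edges
  per <- vapply(xao_relation_types(), function(r)
    sum(e$relation == r), integer(1))
  extra <- sum(!(e$relation %in% xao_relation_types()))

  structure(list(
    total_terms = length(terms),
    anatomical_entities = sum(!(names(terms) %in% stage_ids)),
    developmental_stages = sum(names(terms) %in% stage_ids),
    definitions = sum(vapply(terms, function(t)
      !is.na(t$def) && nzchar(trimws(t$def)), logical(1))),
    synonyms = sum(vapply(terms, function(t)
      nrow(t$synonyms), integer(1))),
    relationship_types = length(unique(e$relation)),
    relationships_total = as.integer(sum(per) + extra),
    per_relation = per,
    xrefs = sum(vapply(terms, function(t)
      length(t$xrefs), integer(1)))),
    class = "xao_stats")
}

#' @export
print.xao_stats <- function(x, ...) {
  cat("Total terms          ", x$total_terms, "\n")
  cat("Anatomical entities  ", x$anatomical_entities, "\n")
  cat("Developmental stages ", x$developmental_stages, "\n")
  cat("Definitions          ", x$definitions, "\n")
  cat("Synonyms             ", x$synonyms, "\n")
  cat("Relationship types   ", x$relationship_types, "\n")
  cat("Relationships        ", x$relationships_total, "\n")
  for (r in names(x$per_relation))
    cat(sprintf("  %-18s %d\n", r, x$per_relation[[r]]))
  cat("Cross-references     ", x$xrefs, "\n")
  invisible(x)
}

#' Format a stats report
#'
#' @param stats An `xao_stats` from [summarize_ontology()].
#' @param format `"tsv"` or `"json"`.
#' @return Character scalar.
#' @export
format_stats <- function(stats, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- c(total_terms = stats$total_terms,
            anatomical_entities = stats$anatomical_entities,
            developmental_stages = stats$developmental_stages,
            definitions = stats$definitions,
            synonyms = stats$synonyms,
            relationship_types = stats$relationship_types,
            relationships_total = stats$relationships_total,
            stats$per_relation,
            xrefs = stats$xrefs)
  if (format == "tsv") {
    paste(c("metric\tcount",
            paste(names(flat), flat, sep = "\t")), collapse = "\n")
  } else {
    jsonlite::toJSON(as.list(flat), auto_unbox = TRUE, pretty = TRUE)
  }
}

.edge_keys <- function(doc) {
  keys <- character(0)
  for (t in doc$terms) {
    if (t$is_obsolete) next
    if (length(t$is_a))
      keys <- c(keys, paste(t$id, "is_a", t$is_a))
    if (nrow(t$relationships))
      keys <- c(keys, paste(t$id, t$relationships$relation,
                            t$relationships$target))
  }
  keys
}

.syn_keys <- function(doc) {
  unlist(lapply(doc$terms, function(t) {
    if (t$is_obsolete || !nrow(t$synonyms)) return(character(0))
    paste(t$id, t$synonyms$label, t$synonyms$scope, sep = "\t")
  }), use.names = FALSE)
}

.xref_keys <- function(doc) {
  unlist(lapply(doc$terms, function(t) {
    if (t$is_obsolete || !length(t$xrefs)) return(character(0))
    paste(t$id, t$xrefs, sep = "\t")
  }), use.names = FALSE)
}

.active_ids <- function(doc) {
  ids <- names(doc$terms)
  ids[!vapply(doc$terms, function(t) t$is_obsolete, logical(1))]
}

#' Diff two ontology releases
#'
#' Set differences between an older and a newer document: terms keyed by
#' id, relationships by (subject, relation, object) triple, synonyms by
#' (term, label, scope), xrefs by (term, xref), plus the ids whose
#' definition text changed. Obsolete stanzas are excluded.
#'
#' @param old_doc,new_doc Parsed [obo_document()]s.
#' @return A list of class `xao_diff` with character-vector fields
#'   `terms_added`, `terms_removed`, `relationships_added`,
#'   `relationships_removed`, `synonyms_added`, `synonyms_removed`,
#'   `xrefs_added`, `xrefs_removed`, `definitions_changed`.
#' @export
diff_releases <- function(old_doc, new_doc) {
  stopifnot(inherits(old_doc, "obo_document"),
            inherits(new_doc, "obo_document"))
  old_ids <- .active_ids(old_doc); new_ids <- .active_ids(new_doc)
  oe <- .edge_keys(old_doc); ne <- .edge_keys(new_doc)
  os <- .syn_keys(old_doc); ns <- .syn_keys(new_doc)
  ox <- .xref_keys(old_doc); nx <- .xref_keys(new_doc)
  common <- intersect(old_ids, new_ids)
  defs_changed <- common[vapply(common, function(i)
    !identical(old_doc$terms[[i]]$def, new_doc$terms[[i]]$def),
    logical(1))]
  structure(list(
    terms_added = sort(setdiff(new_ids, old_ids)),
    terms_removed = sort(setdiff(old_ids, new_ids)),
    relationships_added = sort(setdiff(ne, oe)),
    relationships_removed = sort(setdiff(oe, ne)),
    synonyms_added = sort(setdiff(ns, os)),
    synonyms_removed = sort(setdiff(os, ns)),
    xrefs_added = sort(setdiff(nx, ox)),
    xrefs_removed = sort(setdiff(ox, nx)),
    definitions_changed = sort(defs_changed)),
    class = "xao_diff")
}

#' @export
print.xao_diff <- function(x, ...) {
  for (f in names(x))
    cat(sprintf("%-22s %d\n", f, length(x[[f]])))
  invisible(x)
}

#' @rdname diff_releases
#' @param diff An `xao_diff`.
#' @param format `"tsv"` or `"json"`.
#' @export
format_diff <- function(diff, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    rows <- unlist(lapply(names(diff), function(f)
      if (length(diff[[f]])) paste(f, diff[[f]], sep = "\t")),
      use.names = FALSE)
    paste(c("field\tkey", rows), collapse = "\n")
  } else {
    jsonlite::toJSON(unclass(diff), pretty = TRUE)
  }
}

#' Is a diff empty?
#'
#' @param diff An `xao_diff`.
#' @return `TRUE` when no field contains any entry.
#' @export
diff_is_empty <- function(diff) {
  all(vapply(diff, length, integer(1)) == 0L)
}
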