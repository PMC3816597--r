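# Typed, indexed multigraph over ontology terms with closure computations
# over the classification (is_a), partonomy (part_of) and developmental
# lineage (develops_from) relations.

#' Build a typed term graph from a parsed document
#'
#' Indexes non-obsolete terms by id, name and synonym, collects every
#' asserted edge (`is_a` lines count as `is_a` edges) and quarantines
#' dangling edges — edges whose target id is not an active term — rather
#' than dropping them. Obsolete terms are excluded from the indices but
#' remembered.
#'
#' @param doc An [obo_document()].
#' @return An object of class `xao_graph` with elements `terms` (named list
#'   of active [obo_term()]s), `obsolete` (named list), `edges` and
#'   `dangling` (data frames with columns `subject`, `relation`, `object`),
#'   `name_index` and `synonym_index` (named lists mapping lower-cased
#'   labels to id sets).
#' @export
build_graph <- function(doc) {
  stopifnot(inherits(doc, "obo_document"))
  obs <- vapply(doc$terms, function(t) t$is_obsolete, logical(1))
  terms <- doc$terms[!obs]
  obsolete <- doc$terms[obs]

  edge_list <- lapply(terms, function(t) {
    subj <- character(0); rel <- character(0); obj <- character(0)
    if (length(t$is_a)) {
      subj <- c(subj, rep(t$id, length(t$is_a)))
      rel <- c(rel, rep("is_a", length(t$is_a)))
      obj <- c(obj, t$is_a)
    }
    if (nrow(t$relationships)) {
      subj <- c(subj, rep(t$id, nrow(t$relationships)))
      rel <- c(rel, t$relationships$relation)
      obj <- c(obj, t$relationships$target)
    }
    data.frame(subject = subj, relation = rel, object = obj,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(edge_list, list(
    data.frame(subject = character(), relation = character(),
               object = character(), stringsAsFactors = FALSE))))
  rownames(edges) <- NULL

  dangling <- edges[!(edges$object %in% names(terms)), , drop = FALSE]
  active <- edges[edges$object %in% names(terms), , drop = FALSE]
  rownames(dangling) <- rownames(active) <- NULL

  lower_index <- function(labels, ids) {
    keep <- !is.na(labels)
    split(ids[keep], tolower(labels[keep]))
  }
  name_index <- lower_index(
    vapply(terms, function(t) t$name, character(1)),
    names(terms))
  syn_labels <- unlist(lapply(terms, function(t) t$synonyms$label),
                       use.names = FALSE)
  syn_ids <- unlist(lapply(terms, function(t)
    rep(t$id, nrow(t$synonyms))), use.names = FALSE)
  synonym_index <- lower_index(syn_labels %||% character(), syn_ids %||% character())

  g <- structure(
    list(terms = terms, obsolete = obsolete, edges = edges,
         active_edges = active, dangling = dangling,
         name_index = name_index, synonym_index = synonym_index),
    class = "xao_graph")
  g$adj_up <- .adjacency(active, by = "subject")
  g$adj_down <- .adjacency(active, by = "object")
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-relation adjacency lists: adj[[relation]][[key]] -> neighbor ids
.adjacency <- function(edges, by = c("subject", "object")) {
  by <- match.arg(by)
  to <- if (by == "subject") "object" else "subject"
  out <- list()
  for (r in unique(edges$relation)) {
    e <- edges[edges$relation == r, , drop = FALSE]
    out[[r]] <- split(e[[to]], e[[by]])
  }
  out
}

#' @export
print.xao_graph <- function(x, ...) {
  cat("xao_graph:", length(x$terms), "active terms,",
      length(x$obsolete), "obsolete,", nrow(x$edges), "edges (",
      nrow(x$dangling), "dangling )\n")
  invisible(x)
}

.resolve_id <- function(graph, id, include_obsolete = FALSE) {
  if (id %in% names(graph$terms)) return(id)
  if (include_obsolete && id %in% names(graph$obsolete)) return(id)
  # convenience: allow lookup by exact name
  hit <- graph$name_index[[tolower(id)]]
  if (!is.null(hit) && length(hit) == 1L) return(hit)
  stop("term not found: ", id, call. = FALSE)
}

# BFS over selected relations; adj is graph$adj_up (towards objects,
# ancestors) or graph$adj_down (towards subjects, descendants)
.reach <- function(adj, relations, start) {
  visited <- start
  frontier <- start
  while (length(frontier)) {
    nxt <- character(0)
    for (r in relations) {
      a <- adj[[r]]
      if (is.null(a)) next
      hit <- frontier[frontier %in% names(a)]
      if (length(hit))
        nxt <- c(nxt, unlist(a[hit], use.names = FALSE))
    }
    nxt <- setdiff(unique(nxt), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  setdiff(visited, start)
}

.check_closure_relations <- function(relations) {
  allowed <- c("is_a", "part_of", "develops_from")
  bad <- setdiff(relations, allowed)
  if (length(bad))
    stop("closure relations must be among ",
         paste(allowed, collapse = ", "), "; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' Transitive closure over selected relations
#'
#' `descendants()` returns every term whose chain of selected assertions
#' leads to `id` (e.g. all parts and subtypes below an organ);
#' `ancestors()` traverses the asserted direction, returning the terms `id`
#' leads to. Traversal is union-reachability: a `part_of` hop may follow an
#' `is_a` hop when both relations are selected. No composition reasoning is
#' performed.
#'
#' @param graph An `xao_graph` from [build_graph()].
#' @param id Term id (or unique exact name) to start from.
#' @param relations Subset of `c("is_a", "part_of", "develops_from")`.
#' @param include_self Include `id` itself in the result?
#' @return Character vector of term ids (unsorted).
#' @examples
#' doc <- figure2_fixture()
#' g <- build_graph(doc)
#' kidney <- g$name_index[["pronephric kidney"]]
#' sort(names(g$terms)[names(g$terms) %in% descendants(g, kidney, "part_of")])
#' @export
descendants <- function(graph, id,
                        relations = c("is_a", "part_of", "develops_from"),
                        include_self = FALSE) {
  .check_closure_relations(relations)
  id <- .resolve_id(graph, id)
  res <- .reach(graph$adj_down, relations, id)
  if (include_self) unique(c(id, res)) else res
}

#' @rdname descendants
#' @export
ancestors <- function(graph, id,
                      relations = c("is_a", "part_of", "develops_from"),
                      include_self = FALSE) {
  .check_closure_relations(relations)
  id <- .resolve_id(graph, id)
  res <- .reach(graph$adj_up, relations, id)
  if (include_self) unique(c(id, res)) else res
}
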