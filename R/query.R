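# Ontology-backed search and retrieval: label/synonym search, query
# expansion over classification, partonomy and lineage, stage-range
# filtering, and stage-restricted annotation checking -- the behaviors the
# Xenbase expression search builds on the ontology's assertions.

#' Query expansion options
#'
#' @param include_subtypes Traverse `is_a` downwards (all subtypes of the
#'   query term). On by default: subtype expansion is the backbone of
#'   ontology-based retrieval.
#' @param include_parts Traverse `part_of` downwards, mixed with `is_a`
#'   (a part_of hop may follow an is_a hop).
#' @param include_successors Include developmental derivatives: terms whose
#'   chain of `develops_from` assertions leads back to the query term.
#' @param include_precursors Include developmental precursors: terms the
#'   query term's `develops_from` chain leads to.
#' @param stage_range Optional length-2 vector of stage ids/names
#'   restricting retrieval to an inclusive stage window.
#' @param match_mode Label matching mode for text search: `"exact"`,
#'   `"prefix"` or `"substring"`.
#' @return A list of class `query_options`.
#' @export
query_options <- function(include_subtypes = TRUE, include_parts = FALSE,
                          include_successors = FALSE,
                          include_precursors = FALSE,
                          stage_range = NULL,
                          match_mode = c("substring", "exact", "prefix")) {
  match_mode <- match.arg(match_mode)
  if (!is.null(stage_range) && length(stage_range) != 2L)
    stop("stage_range must be c(start, end)", call. = FALSE)
  structure(list(include_subtypes = isTRUE(include_subtypes),
                 include_parts = isTRUE(include_parts),
                 include_successors = isTRUE(include_successors),
                 include_precursors = isTRUE(include_precursors),
                 stage_range = stage_range, match_mode = match_mode),
            class = "query_options")
}

#' Search terms by name and synonym
#'
#' Case-insensitive matching over term names and synonyms of every scope.
#' Ranking: exact name > exact synonym > prefix > substring; ties are
#' broken alphabetically by term name, then id. `match_mode` restricts
#' which match kinds qualify (`"exact"` admits only exact matches,
#' `"prefix"` adds prefix matches, `"substring"` admits all). With
#' `include_related = TRUE`, terms one `is_a`/`part_of`/`develops_from`
#' edge away from a matched term are appended, flagged as related -- the
#' way an ontology search for a term also surfaces its relational
#' neighborhood.
#'
#' @param graph An `xao_graph`.
#' @param query_text Nonempty query string.
#' @param match_mode `"exact"`, `"prefix"` or `"substring"` (default).
#' @param include_related Append single-hop relational neighbors?
#' @return Data frame with columns `id`, `name`, `matched_label`, `kind`
#'   (`exact_name`, `exact_synonym`, `prefix`, `substring`, `related`).
#' @examples
#' g <- build_graph(figure2_fixture())
#' search_terms(g, "pronephros")$name
#' @export
search_terms <- function(graph, query_text,
                         match_mode = c("substring", "exact", "prefix"),
                         include_related = FALSE) {
  match_mode <- match.arg(match_mode)
  q <- tolower(trimws(query_text))
  if (!nzchar(q)) stop("empty query", call. = FALSE)

  rows <- list()
  for (id in names(graph$terms)) {
    t <- graph$terms[[id]]
    labels <- c(if (!is.na(t$name)) t$name, t$synonyms$label)
    is_name <- c(if (!is.na(t$name)) TRUE, rep(FALSE, nrow(t$synonyms)))
    best_rank <- Inf; best_label <- NA_character_; best_kind <- NA_character_
    for (j in seq_along(labels)) {
      l <- tolower(labels[j])
      kind <- if (l == q) {
        if (is_name[j]) "exact_name" else "exact_synonym"
      } else if (startsWith(l, q)) "prefix"
      else if (grepl(q, l, fixed = TRUE)) "substring"
      else NA_character_
      if (is.na(kind)) next
      rank <- match(kind, c("exact_name", "exact_synonym", "prefix",
                            "substring"))
      if (rank < best_rank) {
        best_rank <- rank; best_label <- labels[j]; best_kind <- kind
      }
    }
    if (is.infinite(best_rank)) next
    max_rank <- switch(match_mode, exact = 2L, prefix = 3L, substring = 4L)
    if (best_rank > max_rank) next
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, name = t$name, matched_label = best_label,
      kind = best_kind, rank = best_rank, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(rows, list(data.frame(
    id = character(), name = character(), matched_label = character(),
    kind = character(), rank = integer(), stringsAsFactors = FALSE))))
  res <- res[order(res$rank, res$name, res$id), , drop = FALSE]

  if (include_related && nrow(res)) {
    e <- graph$active_edges
    e <- e[e$relation %in% c("is_a", "part_of", "develops_from"), ,
           drop = FALSE]
    nb <- unique(c(e$subject[e$object %in% res$id],
                   e$object[e$subject %in% res$id]))
    nb <- setdiff(nb, res$id)
    if (length(nb)) {
      rel <- data.frame(
        id = nb,
        name = vapply(nb, function(i) graph$terms[[i]]$name, character(1)),
        matched_label = NA_character_, kind = "related", rank = 5L,
        stringsAsFactors = FALSE)
      rel <- rel[order(rel$name, rel$id), , drop = FALSE]
      res <- rbind(res, rel)
    }
  }
  rownames(res) <- NULL
  res$rank <- NULL
  res
}

#' Expand a query term over the ontology's relations
#'
#' Starting from the query term, unions in its `is_a` subtypes (unless
#' `include_subtypes` is off), its parts (`part_of` mixed with `is_a`, per
#' the union-reachability closure), its developmental derivatives
#' (`include_successors`: transitive traversal against the `develops_from`
#' direction) and/or its precursors (`include_precursors`: transitive
#' traversal along `develops_from`). With every option off the expansion
#' is just the term itself (exact-match retrieval).
#'
#' @param graph An `xao_graph`.
#' @param id Term id (or unique exact name).
#' @param options A [query_options()].
#' @return Character vector of term ids, always containing `id`.
#' @examples
#' g <- build_graph(figure2_fixture())
#' nc <- g$name_index[["neural crest"]]
#' expand_term(g, nc, query_options(include_successors = TRUE))
#' @export
expand_term <- function(graph, id, options = query_options()) {
  stopifnot(inherits(options, "query_options"))
  id <- .resolve_id(graph, id)

  down <- c(if (options$include_subtypes) "is_a",
            if (options$include_parts) c("is_a", "part_of"),
            if (options$include_successors) "develops_from")
  down <- unique(down)
  up <- if (options$include_precursors) "develops_from" else character(0)

  visited <- id; frontier <- id
  while (length(frontier)) {
    nxt <- character(0)
    for (r in down) {
      a <- graph$adj_down[[r]]
      hit <- frontier[frontier %in% names(a)]
      if (length(hit)) nxt <- c(nxt, unlist(a[hit], use.names = FALSE))
    }
    for (r in up) {
      a <- graph$adj_up[[r]]
      hit <- frontier[frontier %in% names(a)]
      if (length(hit)) nxt <- c(nxt, unlist(a[hit], use.names = FALSE))
    }
    nxt <- setdiff(unique(nxt), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
  }
  visited
}

.resolve_stage <- function(graph, series, s) {
  if (s %in% names(series$index)) return(s)
  i <- match(s, series$names)
  if (!is.na(i)) return(series$ids[i])
  hit <- graph$synonym_index[[tolower(s)]]
  hit <- intersect(hit %||% character(0), series$ids)
  if (length(hit) == 1L) return(hit)
  stop("stage does not resolve in the series: ", s, call. = FALSE)
}

# "a..b" or single stage -> c(start_id, end_id)
.parse_stage_range <- function(graph, series, stage) {
  parts <- strsplit(stage, "..", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, parts)
  r <- c(.resolve_stage(graph, series, parts[1]),
         .resolve_stage(graph, series, parts[2]))
  if (!stage_leq(series, r[1], r[2]))
    stop("stage range start after end: ", stage, call. = FALSE)
  r
}

#' Keep terms whose existence window intersects a stage range
#'
#' @param graph An `xao_graph`.
#' @param series A `stage_series`.
#' @param ids Term ids to filter.
#' @param stage_range Length-2 vector of stage ids/names (inclusive).
#' @return The subset of `ids` whose window shares at least one stage with
#'   the range. Terms without a resolvable window are dropped and listed
#'   in the `"unresolved"` attribute.
#' @export
filter_by_stage <- function(graph, series, ids, stage_range) {
  stopifnot(length(stage_range) == 2L)
  lo <- .resolve_stage(graph, series, stage_range[1])
  hi <- .resolve_stage(graph, series, stage_range[2])
  range_iv <- stage_interval(lo, hi)
  unresolved <- character(0)
  keep <- vapply(ids, function(i) {
    iv <- tryCatch(interval_of(graph, series, i), error = function(e) NULL)
    if (is.null(iv)) { unresolved <<- c(unresolved, i); return(FALSE) }
    interval_intersects(iv, range_iv, series)
  }, logical(1))
  structure(ids[keep], unresolved = unresolved)
}

#' Read / write an annotation corpus
#'
#' Tab-separated corpus with header columns `gene`, `term_id`, `stage_id`,
#' `record_id`; `stage_id` holds one stage or an inclusive range written
#' `start..end`.
#'
#' @param path File path.
#' @return `read_annotations()`: data frame with the four columns.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("gene", "term_id", "stage_id", "record_id")
  if (!all(need %in% names(df)))
    stop("annotation corpus must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df[, need]
}

#' @rdname read_annotations
#' @param annotations Data frame as returned by [read_annotations()] or
#'   [generate_corpus()].
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Retrieve annotations by ontology-expanded query
#'
#' Returns the corpus rows whose term lies in the expansion of the query
#' term under `options`, optionally restricted to rows whose annotation
#' stage (every stage of a range must overlap) intersects
#' `options$stage_range`. With all expansion options off this degenerates
#' to exact term equality. Rows whose term id does not resolve in the
#' graph are never silently dropped: they are returned in the
#' `"unresolved"` attribute.
#'
#' @param graph An `xao_graph`.
#' @param series A `stage_series`.
#' @param corpus Annotation data frame (see [read_annotations()]).
#' @param id Query term id (or unique exact name).
#' @param options A [query_options()].
#' @return The matching subset of `corpus`, with attribute `"unresolved"`
#'   holding the unresolvable rows.
#' @export
retrieve_annotations <- function(graph, series, corpus, id,
                                 options = query_options()) {
  id <- .resolve_id(graph, id)
  ids <- expand_term(graph, id, options)
  resolvable <- corpus$term_id %in% c(names(graph$terms),
                                      names(graph$obsolete))
  unresolved <- corpus[!resolvable, , drop = FALSE]
  hits <- corpus[resolvable & corpus$term_id %in% ids, , drop = FALSE]
  if (!is.null(options$stage_range)) {
    lo <- .resolve_stage(graph, series, options$stage_range[1])
    hi <- .resolve_stage(graph, series, options$stage_range[2])
    qiv <- stage_interval(lo, hi)
    keep <- vapply(seq_len(nrow(hits)), function(r) {
      rng <- .parse_stage_range(graph, series, hits$stage_id[r])
      interval_intersects(stage_interval(rng[1], rng[2]), qiv, series)
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  structure(hits, unresolved = unresolved)
}

#' Check an annotation against its term's existence window
#'
#' An expression annotation is valid when every stage it is annotated to
#' (a single stage, or each end of an inclusive `start..end` range) lies
#' within the annotated term's `starts_during`/`ends_during` window, both
#' ends inclusive -- the stage restriction the curation interface imposes.
#' An unresolvable term or stage is an error (a resolution failure), never
#' an invalid verdict.
#'
#' @param graph An `xao_graph`.
#' @param series A `stage_series`.
#' @param term Annotated term id or unique exact name.
#' @param stage Stage id/name, or range `"start..end"`.
#' @param gene,record Optional provenance carried into the result.
#' @return A list of class `annotation_check`: `valid` flag, `term`,
#'   `stage`, `gene`, `record`, `interval` (the term's window) and
#'   `reason` (`NA` when valid).
#' @examples
#' g <- build_graph(figure2_fixture())
#' s <- build_stage_series(g)
#' check_annotation(g, s, "early distal tubule", "NF stage 37/38")$valid
#' @export
check_annotation <- function(graph, series, term, stage,
                             gene = NA_character_, record = NA_character_) {
  term <- .resolve_id(graph, term)
  rng <- .parse_stage_range(graph, series, stage)
  iv <- interval_of(graph, series, term)
  ok <- interval_within(stage_interval(rng[1], rng[2]), iv, series)
  reason <- if (ok) NA_character_ else
    paste0("stage ", stage, " outside the window [",
           series$names[stage_index(series, iv$start)], ", ",
           series$names[stage_index(series, iv$end)], "] of '",
           .label(graph, term), "'")
  structure(list(valid = ok, term = term, stage = stage, gene = gene,
                 record = record, interval = iv, reason = reason),
            class = "annotation_check")
}

#' @export
print.annotation_check <- function(x, ...) {
  cat(if (x$valid) "VALID" else "INVALID", ":",
      if (!is.na(x$gene)) x$gene, "@", x$stage, "in",
      x$term, "\n")
  if (!x$valid) cat("  ", x$reason, "\n")
  invisible(x)
}

#' Check every row of an annotation corpus
#'
#' @inheritParams retrieve_annotations
#' @return Data frame: the corpus plus `status` (`"valid"`, `"invalid"` or
#'   `"unresolved"`) and `reason` columns.
#' @export
check_corpus <- function(graph, series, corpus) {
  status <- character(nrow(corpus)); reason <- character(nrow(corpus))
  for (r in seq_len(nrow(corpus))) {
    res <- tryCatch(
      check_annotation(graph, series, corpus$term_id[r],
                       corpus$stage_id[r], corpus$gene[r],
                       corpus$record_id[r]),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[r] <- "unresolved"; reason[r] <- conditionMessage(res)
    } else {
      status[r] <- if (res$valid) "valid" else "invalid"
      reason[r] <- res$reason %||NA% ""
    }
  }
  out <- corpus
  out$status <- status
  out$reason <- reason
  out
}
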