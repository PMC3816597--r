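# Nieuwkoop-Faber stage series as a linear chain ordered by preceded_by,
# plus inclusive interval arithmetic for per-term existence windows.

.STAGE_NAMESPACE <- "xenopus_developmental_stage"

# stage terms: by namespace tag when present, else participants of
# preceded_by edges, else targets of starts_during/ends_during
.stage_term_ids <- function(graph) {
  ns <- vapply(graph$terms, function(t)
    identical(t$namespace, .STAGE_NAMESPACE), logical(1))
  if (any(ns)) return(names(graph$terms)[ns])
  e <- graph$edges
  pb <- e[e$relation == "preceded_by", , drop = FALSE]
  if (nrow(pb)) return(unique(c(pb$subject, pb$object)))
  st <- e[e$relation %in% c("starts_during", "ends_during"), , drop = FALSE]
  unique(st$object)
}

#' Build the developmental stage series
#'
#' Orders the stage sub-ontology into one linear chain using the
#' `preceded_by` links (each stage is preceded by its unique predecessor).
#' The ordinal assignment depends only on the links, not on stanza order.
#' Oogenesis stages come before `NF stage 1` and a terminal sentinel such
#' as `death` follows `NF stage 66` simply by being linked into the chain;
#' any stage term that cannot be linked is an error, never silently
#' accepted.
#'
#' @param graph An `xao_graph` from [build_graph()].
#' @return An object of class `stage_series`: list with `ids` (ordered
#'   stage term ids), `names` (their labels), `index` (named integer map
#'   id -> ordinal, 1-based).
#' @examples
#' g <- build_graph(nf_stage_chain(66))
#' s <- build_stage_series(g)
#' length(s$ids)
#' @export
build_stage_series <- function(graph) {
  ids <- .stage_term_ids(graph)
  if (!length(ids))
    stop("no stage terms found in graph", call. = FALSE)
  e <- graph$edges
  pb <- e[e$relation == "preceded_by" & e$subject %in% ids, , drop = FALSE]
  if (any(!(pb$object %in% ids)))
    stop("preceded_by target is not a stage term: ",
         paste(setdiff(pb$object, ids), collapse = ", "), call. = FALSE)

  pred <- pb$object; names(pred) <- pb$subject
  if (anyDuplicated(pb$subject))
    stop("stage has multiple predecessors: ",
         paste(unique(pb$subject[duplicated(pb$subject)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(pb$object))
    stop("stage has multiple successors: ",
         paste(unique(pb$object[duplicated(pb$object)]), collapse = ", "),
         call. = FALSE)
  succ <- pb$subject; names(succ) <- pb$object

  starts <- setdiff(ids, pb$subject)     # stages with no predecessor
  if (length(ids) > 1L && length(starts) != 1L)
    stop("preceded_by chain is not linear; chain starts: ",
         paste(starts, collapse = ", "), call. = FALSE)
  start <- if (length(ids) == 1L) ids else starts

  chain <- character(length(ids))
  cur <- start
  for (i in seq_along(ids)) {
    if (is.na(cur))
      stop("preceded_by chain is cyclic or broken; unlinked stages: ",
           paste(setdiff(ids, chain[seq_len(i - 1L)]), collapse = ", "),
           call. = FALSE)
    if (cur %in% chain[seq_len(i - 1L)])
      stop("preceded_by chain is cyclic at: ", cur, call. = FALSE)
    chain[i] <- cur
    cur <- if (cur %in% names(succ)) succ[[cur]] else NA_character_
  }
  if (!is.na(cur) || !setequal(chain, ids))
    stop("stage terms not linkable into one chain: ",
         paste(setdiff(ids, chain), collapse = ", "), call. = FALSE)

  idx <- seq_along(chain); names(idx) <- chain
  nm <- vapply(chain, function(i) graph$terms[[i]]$name, character(1))
  structure(list(ids = chain, names = unname(nm), index = idx),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat("stage_series of", length(x$ids), "stages:", x$names[1], "...",
      x$names[length(x$names)], "\n")
  invisible(x)
}

#' Resolve a stage (id or name) to its ordinal in the series
#'
#' @param series A `stage_series`.
#' @param s Stage term id or exact stage name (e.g. `"NF stage 28"`).
#' @return Integer ordinal (1-based), or `NA` if `s` is not in the series.
#' @export
stage_index <- function(series, s) {
  if (s %in% names(series$index)) return(unname(series$index[[s]]))
  hit <- which(series$names == s)
  if (length(hit) == 1L) return(hit)
  NA_integer_
}

#' Compare two stages by temporal order
#'
#' @inheritParams stage_index
#' @param a,b Stage ids or names.
#' @return `TRUE` iff `a` is the same stage as, or earlier than, `b`.
#' @export
stage_leq <- function(series, a, b) {
  ia <- stage_index(series, a); ib <- stage_index(series, b)
  if (is.na(ia) || is.na(ib))
    stop("stage not in series: ", if (is.na(ia)) a else b, call. = FALSE)
  ia <= ib
}

#' The stage immediately following `s`
#'
#' @inheritParams stage_index
#' @return Stage id of the unique successor, or `NA` at the chain end.
#' @export
next_stage <- function(series, s) {
  i <- stage_index(series, s)
  if (is.na(i)) stop("stage not in series: ", s, call. = FALSE)
  if (i >= length(series$ids)) return(NA_character_)
  series$ids[i + 1L]
}

#' Stage interval constructor
#'
#' An inclusive existence window `[start, end]` on the stage chain.
#'
#' @param start,end Stage ids.
#' @return A `stage_interval` object.
#' @export
stage_interval <- function(start, end) {
  structure(list(start = start, end = end), class = "stage_interval")
}

#' @export
print.stage_interval <- function(x, ...) {
  cat("[", x$start, ", ", x$end, "]\n", sep = "")
  invisible(x)
}

#' Existence window of an anatomical term
#'
#' Resolves the term's `starts_during` and `ends_during` assertions against
#' the stage series. A term must carry exactly one of each.
#'
#' @param graph An `xao_graph`.
#' @param series A `stage_series`.
#' @param term_id Anatomy term id (or unique exact name).
#' @return A [stage_interval()] whose endpoints are stage ids in `series`.
#' @examples
#' doc <- figure2_fixture()
#' g <- build_graph(doc)
#' s <- build_stage_series(g)
#' interval_of(g, s, "pronephric kidney")
#' @export
interval_of <- function(graph, series, term_id) {
  term_id <- .resolve_id(graph, term_id)
  e <- graph$edges
  st <- e$object[e$subject == term_id & e$relation == "starts_during"]
  en <- e$object[e$subject == term_id & e$relation == "ends_during"]
  if (length(st) == 0L || length(en) == 0L)
    stop("incomplete stage assertions for ", term_id,
         ": needs one starts_during and one ends_during", call. = FALSE)
  if (length(st) > 1L || length(en) > 1L)
    stop("ambiguous stage assertions for ", term_id,
         ": multiple starts_during/ends_during", call. = FALSE)
  if (is.na(stage_index(series, st)) || is.na(stage_index(series, en)))
    stop("stage not in series for ", term_id, ": ",
         paste(c(st, en)[is.na(c(stage_index(series, st),
                                 stage_index(series, en)))],
               collapse = ", "), call. = FALSE)
  stage_interval(st, en)
}

#' Interval containment
#'
#' Is `inner` the same as, or wholly within, `outer`? Both ends are
#' inclusive: `[NF21, NF30]` is within `[NF21, NF30]`.
#'
#' @param inner,outer [stage_interval()] objects.
#' @param series A `stage_series`.
#' @return `TRUE` or `FALSE`.
#' @export
interval_within <- function(inner, outer, series) {
  stage_leq(series, outer$start, inner$start) &&
    stage_leq(series, inner$end, outer$end)
}

#' Interval overlap
#'
#' Do the two inclusive intervals share at least one stage?
#'
#' @inheritParams interval_within
#' @param a,b [stage_interval()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
interval_intersects <- function(a, b, series) {
  stage_leq(series, a$start, b$end) && stage_leq(series, b$start, a$end)
}
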