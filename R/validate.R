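# Ontology-building rule suite: the consistency rules that keep
# developmental timing of related terms biologically sensible, plus
# structural hygiene (definitions, parents, dangling edges, acyclicity).

.RULE_CODES <- paste0("R", 1:10)

.default_severities <- function() {
  sev <- rep("error", 10L)
  names(sev) <- .RULE_CODES
  sev["R6"] <- "warning"   # timing governs part_of validity, but no
                           # containment formula is asserted outright
  sev
}

#' Configuration for [validate()]
#'
#' @param rules Character vector of rule codes to enable (default all ten).
#' @param severities Named character vector overriding per-rule severities
#'   (`"error"` or `"warning"`). By default every rule is an error except
#'   R6 (part_of containment), a warning.
#' @param r5_slack How many stages after its precursor's end a structure
#'   may first appear (R5's "immediately after"); default 1.
#' @param roots Term ids or exact names exempt from the is_a-parent rule
#'   (R2) and the part_of/develops_from completeness rule (R7). Default is
#'   the CARO-style upper node `"anatomical entity"`.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(rules = .RULE_CODES,
                              severities = character(),
                              r5_slack = 1L,
                              roots = "anatomical entity") {
  bad <- setdiff(rules, .RULE_CODES)
  if (length(bad))
    stop("unknown rule code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sev <- .default_severities()
  if (length(severities)) {
    bad <- setdiff(names(severities), .RULE_CODES)
    if (length(bad))
      stop("unknown rule code(s) in severities: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!all(severities %in% c("error", "warning")))
      stop("severities must be 'error' or 'warning'", call. = FALSE)
    sev[names(severities)] <- severities
  }
  structure(list(rules = rules, severities = sev,
                 r5_slack = as.integer(r5_slack), roots = roots),
            class = "validation_config")
}

.rule_texts <- c(
  R1 = paste("R1 (definition completeness): every non-obsolete term must",
             "have a nonempty textual definition, so curators can be",
             "certain they are selecting the correct term."),
  R2 = paste("R2 (classification completeness): every non-root term must",
             "have at least one is_a parent; the ontology is a single",
             "classification framework, not a bare partonomy."),
  R3 = paste("R3 (timing completeness): every anatomical term must carry",
             "exactly one starts_during and one ends_during stage",
             "assertion, with the start stage not after the end stage."),
  R4 = paste("R4 (is_a stage containment): a child term's existence window",
             "must be the same as or fall within that of its is_a parent",
             "(e.g. pronephric mesenchyme within mesenchyme)."),
  R5 = paste("R5 (develops_from timing): a structure must first appear",
             "sometime within or immediately after the stage range of the",
             "precursor it develops_from (at most a configurable number of",
             "stages - default one - past the precursor's end)."),
  R6 = paste("R6 (part_of timing): the validity of part_of relationships",
             "is governed by the timing of the related terms; a part's",
             "existence window should lie within its whole's window."),
  R7 = paste("R7 (relational completeness): every anatomical term, or one",
             "of its is_a ancestors, must have at least one part_of and at",
             "least one develops_from relationship to another term."),
  R8 = paste("R8 (referential integrity): every relationship target must",
             "resolve to a term in the ontology; dangling edges are",
             "quarantined and reported."),
  R9 = paste("R9 (acyclicity): the combined is_a / part_of / develops_from",
             "subgraph must be a directed acyclic graph."),
  R10 = paste("R10 (stage resolution): every stage referenced by",
              "starts_during or ends_during must resolve to a stage in the",
              "developmental stage series.")
)

#' Explain a validation rule
#'
#' @param rule_code One of `"R1"` ... `"R10"`.
#' @return Human-readable statement of the rule.
#' @export
explain_rule <- function(rule_code) {
  if (!(rule_code %in% .RULE_CODES))
    stop("unknown rule code: ", rule_code, call. = FALSE)
  unname(.rule_texts[[rule_code]])
}

# interval bookkeeping tolerant of missing/duplicated/unresolvable edges;
# returns per-term list(start, end, si, ei, n_start, n_end, ok)
.term_timing <- function(graph, series, ids) {
  e <- graph$edges
  st <- e[e$relation == "starts_during", , drop = FALSE]
  en <- e[e$relation == "ends_during", , drop = FALSE]
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    s <- st$object[st$subject == id]
    n <- en$object[en$subject == id]
    si <- if (length(s) == 1L) stage_index(series, s) else NA_integer_
    ei <- if (length(n) == 1L) stage_index(series, n) else NA_integer_
    out[[id]] <- list(start = if (length(s) == 1L) s else NA_character_,
                      end = if (length(n) == 1L) n else NA_character_,
                      si = si, ei = ei,
                      n_start = length(s), n_end = length(n),
                      ok = length(s) == 1L && length(n) == 1L &&
                        !is.na(si) && !is.na(ei))
  }
  out
}

#' Validate an ontology against the stage-consistency rule suite
#'
#' Applies the enabled rules (see [explain_rule()]) and returns every
#' finding as a report entry; nothing is thrown for rule violations. The
#' report is deterministic: entries are ordered by rule code, then subject.
#'
#' @param graph An `xao_graph` from [build_graph()].
#' @param series A `stage_series` from [build_stage_series()]; built from
#'   `graph` when omitted (an unresolvable series is then an error).
#' @param config A [validation_config()].
#' @return A `validation_report`: list with `violations` (data frame with
#'   columns `rule`, `severity`, `subject`, `message`), `counts` (named
#'   integer per rule), `terms_checked`, and `valid` (no violations).
#' @examples
#' g <- build_graph(figure2_fixture())
#' validate(g)$valid
#' @export
validate <- function(graph, series = NULL, config = validation_config()) {
  stopifnot(inherits(graph, "xao_graph"))
  if (is.null(series)) series <- build_stage_series(graph)
  if (!inherits(config, "validation_config"))
    stop("config must be a validation_config()", call. = FALSE)

  stage_ids <- names(series$index)
  anat <- setdiff(names(graph$terms), stage_ids)
  root_ids <- unique(c(
    intersect(config$roots, names(graph$terms)),
    unlist(graph$name_index[tolower(config$roots)], use.names = FALSE)))

  rule <- character(); subject <- character(); message <- character()
  add <- function(code, subj, msg) {
    rule <<- c(rule, code); subject <<- c(subject, subj)
    message <<- c(message, msg)
  }

  timing <- .term_timing(graph, series, anat)
  e <- graph$active_edges

  if ("R1" %in% config$rules) {
    for (id in names(graph$terms)) {
      t <- graph$terms[[id]]
      if (is.na(t$def) || !nzchar(trimws(t$def)))
        add("R1", id, paste0("term '", t$name %||NA% id,
                             "' has no definition"))
    }
  }

  if ("R2" %in% config$rules) {
    for (id in setdiff(anat, root_ids)) {
      if (!length(graph$terms[[id]]$is_a))
        add("R2", id, paste0("non-root term '", .label(graph, id),
                             "' has no is_a parent"))
    }
  }

  if ("R3" %in% config$rules) {
    for (id in anat) {
      ti <- timing[[id]]
      if (ti$n_start != 1L || ti$n_end != 1L) {
        add("R3", id, paste0("term '", .label(graph, id), "' has ",
                             ti$n_start, " starts_during and ", ti$n_end,
                             " ends_during assertions (need exactly one each)"))
      } else if (!is.na(ti$si) && !is.na(ti$ei) && ti$si > ti$ei) {
        add("R3", id, paste0("term '", .label(graph, id), "' starts (",
                             ti$start, ") after it ends (", ti$end, ")"))
      }
    }
  }

  if ("R4" %in% config$rules) {
    isa <- e[e$relation == "is_a" &
               e$subject %in% anat & e$object %in% anat, , drop = FALSE]
    for (k in seq_len(nrow(isa))) {
      ch <- timing[[isa$subject[k]]]; pa <- timing[[isa$object[k]]]
      if (is.null(ch) || is.null(pa) || !ch$ok || !pa$ok) next
      if (ch$si < pa$si || ch$ei > pa$ei)
        add("R4", paste(isa$subject[k], "is_a", isa$object[k]),
            paste0("interval of '", .label(graph, isa$subject[k]), "' [",
                   ch$start, ", ", ch$end,
                   "] is not within its is_a parent '",
                   .label(graph, isa$object[k]), "' [", pa$start, ", ",
                   pa$end, "]"))
    }
  }

  if ("R5" %in% config$rules) {
    df <- e[e$relation == "develops_from" &
              e$subject %in% anat & e$object %in% anat, , drop = FALSE]
    for (k in seq_len(nrow(df))) {
      x <- timing[[df$subject[k]]]; y <- timing[[df$object[k]]]
      if (is.null(x) || is.null(y) || !x$ok || !y$ok) next
      if (x$si < y$si || x$si > y$ei + config$r5_slack)
        add("R5", paste(df$subject[k], "develops_from", df$object[k]),
            paste0("'", .label(graph, df$subject[k]), "' starts at ",
                   x$start, ", outside [", y$start, ", ",
                   "next(", y$end, ")] allowed by its precursor '",
                   .label(graph, df$object[k]), "'"))
    }
  }

  if ("R6" %in% config$rules) {
    po <- e[e$relation == "part_of" &
              e$subject %in% anat & e$object %in% anat, , drop = FALSE]
    for (k in seq_len(nrow(po))) {
      part <- timing[[po$subject[k]]]; whole <- timing[[po$object[k]]]
      if (is.null(part) || is.null(whole) || !part$ok || !whole$ok) next
      if (part$si < whole$si || part$ei > whole$ei)
        add("R6", paste(po$subject[k], "part_of", po$object[k]),
            paste0("interval of part '", .label(graph, po$subject[k]),
                   "' [", part$start, ", ", part$end,
                   "] is not within its whole '",
                   .label(graph, po$object[k]), "' [", whole$start, ", ",
                   whole$end, "]"))
    }
  }

  if ("R7" %in% config$rules) {
    has_po <- unique(e$subject[e$relation == "part_of"])
    has_df <- unique(e$subject[e$relation == "develops_from"])
    for (id in setdiff(anat, root_ids)) {
      closure <- c(id, .reach(graph$adj_up, "is_a", id))
      miss <- c(if (!any(closure %in% has_po)) "part_of",
                if (!any(closure %in% has_df)) "develops_from")
      if (length(miss))
        add("R7", id, paste0("term '", .label(graph, id),
                             "' and its is_a ancestors lack any ",
                             paste(miss, collapse = " and "),
                             " relationship"))
    }
  }

  if ("R8" %in% config$rules) {
    d <- graph$dangling
    for (k in seq_len(nrow(d)))
      add("R8", paste(d$subject[k], d$relation[k], d$object[k]),
          paste0("edge target '", d$object[k],
                 "' does not resolve to an active term"))
  }

  if ("R9" %in% config$rules) {
    u <- e[e$relation %in% c("is_a", "part_of", "develops_from"), ,
           drop = FALSE]
    cyc <- .cyclic_nodes(u)
    if (length(cyc)) {
      for (comp in .weak_components(u, cyc))
        add("R9", paste(sort(comp), collapse = ","),
            paste0("cycle in is_a/part_of/develops_from subgraph through: ",
                   paste(sort(comp), collapse = ", ")))
    }
  }

  if ("R10" %in% config$rules) {
    se <- e[e$relation %in% c("starts_during", "ends_during"), ,
            drop = FALSE]
    bad <- se[!(se$object %in% stage_ids), , drop = FALSE]
    for (k in seq_len(nrow(bad)))
      add("R10", paste(bad$subject[k], bad$relation[k], bad$object[k]),
          paste0("'", bad$object[k],
                 "' is not a stage in the developmental stage series"))
  }

  sev <- unname(config$severities[rule])
  v <- data.frame(rule = rule, severity = sev %||chr% character(),
                  subject = subject, message = message,
                  stringsAsFactors = FALSE)
  v <- v[order(v$rule, v$subject, v$message), , drop = FALSE]
  rownames(v) <- NULL
  counts <- vapply(.RULE_CODES, function(r) sum(v$rule == r), integer(1))
  structure(list(violations = v, counts = counts,
                 terms_checked = length(graph$terms),
                 valid = nrow(v) == 0L),
            class = "validation_report")
}

`%||NA%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
`%||chr%` <- function(a, b) if (length(a)) a else b

.label <- function(graph, id) {
  t <- graph$terms[[id]]
  if (is.null(t) || is.na(t$name)) id else t$name
}

# nodes lying on (or between) directed cycles: intersection of the nodes
# that Kahn peeling cannot remove in the forward and backward directions
.cyclic_nodes <- function(edges) {
  if (!nrow(edges)) return(character())
  peel <- function(from, to) {
    nodes <- unique(c(from, to))
    alive <- rep(TRUE, nrow(edges))
    repeat {
      indeg_nodes <- unique(to[alive])
      removable <- setdiff(nodes, indeg_nodes)
      if (!length(removable)) break
      nodes <- setdiff(nodes, removable)
      alive <- alive & !(from %in% removable)
      if (!length(nodes)) break
    }
    nodes
  }
  fwd <- peel(edges$object, edges$subject)   # peel leaves upward
  bwd <- peel(edges$subject, edges$object)
  intersect(fwd, bwd)
}

# weakly-connected components of `nodes` within the given edge set
.weak_components <- function(edges, nodes) {
  adj <- list()
  sub <- edges[edges$subject %in% nodes & edges$object %in% nodes, ,
               drop = FALSE]
  for (k in seq_len(nrow(sub))) {
    adj[[sub$subject[k]]] <- c(adj[[sub$subject[k]]], sub$object[k])
    adj[[sub$object[k]]] <- c(adj[[sub$object[k]]], sub$subject[k])
  }
  comps <- list(); left <- nodes
  while (length(left)) {
    comp <- left[1]; frontier <- comp
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), comp)
      comp <- c(comp, nxt); frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- comp
    left <- setdiff(left, comp)
  }
  comps
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) {
    cat("Valid:", x$terms_checked, "terms checked, no violations\n")
  } else {
    cat(nrow(x$violations), "violation(s) over", x$terms_checked,
        "terms:\n")
    print(x$violations, right = FALSE)
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' @param report A `validation_report` from [validate()].
#' @param format `"tsv"` or `"json"`.
#' @return Character scalar (TSV with header, or JSON).
#' @export
format_report <- function(report, format = c("tsv", "json")) {
  format <- match.arg(format)
  v <- report$violations
  if (format == "tsv") {
    header <- "rule\tseverity\tsubject\tmessage"
    if (!nrow(v)) return(header)
    paste(c(header, paste(v$rule, v$severity, v$subject, v$message,
                          sep = "\t")), collapse = "\n")
  } else {
    jsonlite::toJSON(list(valid = report$valid,
                          terms_checked = report$terms_checked,
                          counts = as.list(report$counts),
                          violations = v),
                     auto_unbox = TRUE, pretty = TRUE)
  }
}
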