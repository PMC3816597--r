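# shared fixtures, built once per test run

fig2_doc <- figure2_fixture()
fig2_graph <- build_graph(fig2_doc)
fig2_series <- build_stage_series(fig2_graph)

# resolve a term id in the worked-example fixture by its name
fid <- function(name) {
  hit <- fig2_graph$name_index[[tolower(name)]]
  stopifnot(length(hit) == 1L)
  hit
}

# brute-force reachability oracle: fixpoint over an edge table, kept
# independent of the adjacency-list BFS inside the package
bf_reach <- function(edges, start, relations, direction = c("down", "up")) {
  direction <- match.arg(direction)
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  from <- if (direction == "down") e$object else e$subject
  to <- if (direction == "down") e$subject else e$object
  out <- character(0)
  frontier <- start
  repeat {
    nxt <- setdiff(unique(to[from %in% frontier]), c(out, start))
    if (!length(nxt)) break
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# brute-force expansion oracle mirroring the documented option semantics
bf_expand <- function(graph, id, opts) {
  e <- graph$active_edges
  res <- id
  repeat {
    add <- character(0)
    if (opts$include_subtypes || opts$include_parts) {
      rels <- c("is_a", if (opts$include_parts) "part_of")
      sub <- e[e$relation %in% rels & e$object %in% res, , drop = FALSE]
      add <- c(add, sub$subject)
    }
    if (opts$include_successors) {
      sub <- e[e$relation == "develops_from" & e$object %in% res, ,
               drop = FALSE]
      add <- c(add, sub$subject)
    }
    if (opts$include_precursors) {
      sub <- e[e$relation == "develops_from" & e$subject %in% res, ,
               drop = FALSE]
      add <- c(add, sub$object)
    }
    add <- setdiff(unique(add), res)
    if (!length(add)) break
    res <- c(res, add)
  }
  res
}
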