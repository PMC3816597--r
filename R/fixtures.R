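# Deterministic generators for test ontologies and annotation corpora:
# an NF stage chain, a small hand-built pronephric-kidney ontology, random
# rule-conformant ontologies, seeded violation injection, and corpora of
# stage-checked expression annotations.

.XAOT_PREFIX <- "XAOT"   # reserved test id prefix, never collides with XAO:

.xaot_id <- function(n) sprintf("%s:%07d", .XAOT_PREFIX, n)
.stage_id <- function(n) sprintf("%s:%07d", .XAOT_PREFIX, 1000000L + n)

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.relation_typedefs <- function() {
  lapply(xao_relation_types(), function(r)
    list(id = r, name = gsub("_", " ", r), other = character()))
}

.fixture_header <- function() {
  c("format-version: 1.2",
    "default-namespace: xenopus_anatomy")
}

#' Generate the Nieuwkoop-Faber stage chain
#'
#' Builds `n` stage term stanzas named `NF stage 1` ... `NF stage n`, each
#' stage after the first linked to its predecessor by `preceded_by`, all in
#' the `xenopus_developmental_stage` namespace. When `n = 66` (the full
#' series) the composite-stage label `NF stage 37/38` is attached to
#' `NF stage 37` as an EXACT synonym, so annotations staged on the
#' composite entry of the normal table resolve.
#'
#' @param n Number of stages (default 66, the full series).
#' @return An [obo_document()] of `n` stage stanzas plus the six relation
#'   typedefs.
#' @export
nf_stage_chain <- function(n = 66L) {
  stopifnot(n >= 1L)
  terms <- vector("list", n)
  for (i in seq_len(n)) {
    syn <- empty_synonyms()
    if (n == 66L && i == 37L)
      syn <- data.frame(label = "NF stage 37/38", scope = "EXACT",
                        stringsAsFactors = FALSE)
    rel <- if (i == 1L) empty_relationships() else
      data.frame(relation = "preceded_by", target = .stage_id(i - 1L),
                 stringsAsFactors = FALSE)
    terms[[i]] <- obo_term(
      id = .stage_id(i),
      name = paste("NF stage", i),
      namespace = .STAGE_NAMESPACE,
      def = paste0("Developmental stage ", i,
                   " of the Nieuwkoop and Faber normal table."),
      synonyms = syn,
      relationships = rel)
  }
  obo_document(header = .fixture_header(), terms = terms,
               typedefs = .relation_typedefs())
}

# append a terminal sentinel stage after the last stage of `doc`
.add_sentinel <- function(doc, name = "death", after_n) {
  id <- .stage_id(after_n + 1L)
  doc$terms[[id]] <- obo_term(
    id = id, name = name, namespace = .STAGE_NAMESPACE,
    def = "Terminal sentinel stage: the end of the life cycle.",
    relationships = data.frame(relation = "preceded_by",
                               target = .stage_id(after_n),
                               stringsAsFactors = FALSE))
  doc
}

# anatomical term helper used by the hand-built and random fixtures;
# start/end are stage ordinals resolved against .stage_id()
.anat_term <- function(id, name, def, is_a = character(),
                       part_of = character(), develops_from = character(),
                       start = NA, end = NA, synonyms = empty_synonyms(),
                       xrefs = character()) {
  rel <- empty_relationships()
  if (length(part_of))
    rel <- rbind(rel, data.frame(relation = "part_of", target = part_of,
                                 stringsAsFactors = FALSE))
  if (length(develops_from))
    rel <- rbind(rel, data.frame(relation = "develops_from",
                                 target = develops_from,
                                 stringsAsFactors = FALSE))
  if (!is.na(start))
    rel <- rbind(rel, data.frame(relation = "starts_during",
                                 target = .stage_id(start),
                                 stringsAsFactors = FALSE))
  if (!is.na(end))
    rel <- rbind(rel, data.frame(relation = "ends_during",
                                 target = .stage_id(end),
                                 stringsAsFactors = FALSE))
  obo_term(id = id, name = name, def = def,
           def_xrefs = character(), synonyms = synonyms, xrefs = xrefs,
           is_a = is_a, relationships = rel)
}

#' The packaged pronephric-kidney worked-example ontology
#'
#' A small hand-built ontology around the pronephric kidney and its
#' relatives, with the full 66-stage NF chain plus a `death` sentinel. It
#' encodes the canonical XAO assertions: `pronephric mesenchyme` (window
#' NF 21-30) is a type of `mesenchyme`; `pronephric kidney` develops from
#' `pronephric mesenchyme` and exists from NF stage 28 to NF stage 64; its
#' tubules, duct and nephrostome are parts of it; the transient
#' `tail region` spans NF 26-66; the adult `mesonephric kidney` runs from
#' NF 39 to `death`. A heart / cardiac mesoderm pair, a brain / forebrain
#' pair and a neural crest lineage support search and expansion examples.
#' The document satisfies every validation rule.
#'
#' @return An [obo_document()].
#' @examples
#' g <- build_graph(figure2_fixture())
#' validate(g)$valid
#' @export
figure2_fixture <- function() {
  doc <- nf_stage_chain(66L)
  doc <- .add_sentinel(doc, "death", 66L)
  DEATH <- 67L

  add <- function(doc, t) { doc$terms[[t$id]] <- t; doc }
  id <- function(n) .xaot_id(n)

  doc <- add(doc, .anat_term(id(1), "anatomical entity",
    "Upper-level root class for anatomical entities.",
    start = 1, end = DEATH))
  doc <- add(doc, .anat_term(id(2), "anatomical structure",
    "Material anatomical entity with inherent 3D shape.",
    is_a = id(1), part_of = id(1), develops_from = id(1),
    start = 1, end = DEATH,
    xrefs = "CARO:0000003"))
  doc <- add(doc, .anat_term(id(3), "mesenchyme",
    "Loosely organized tissue of dispersed cells in extracellular matrix.",
    is_a = id(2), start = 10, end = 66,
    xrefs = "UBERON:0003104"))
  doc <- add(doc, .anat_term(id(4), "pronephric mesenchyme",
    "Mesenchyme that condenses to form the pronephric kidney.",
    is_a = id(3), start = 21, end = 30))
  doc <- add(doc, .anat_term(id(5), "pronephric kidney",
    "Embryonic kidney of the larva, resorbed at metamorphosis.",
    is_a = id(2), develops_from = id(4), start = 28, end = 64,
    synonyms = data.frame(label = "pronephros", scope = "EXACT",
                          stringsAsFactors = FALSE),
    xrefs = "UBERON:0002120"))
  doc <- add(doc, .anat_term(id(6), "early distal tubule",
    "Distal tubule of the early pronephric kidney.",
    is_a = id(2), part_of = id(5), start = 32, end = 44))
  doc <- add(doc, .anat_term(id(7), "early proximal tubule",
    "Proximal tubule of the early pronephric kidney.",
    is_a = id(2), part_of = id(5), start = 30, end = 39))
  doc <- add(doc, .anat_term(id(8), "late proximal tubule",
    "Proximal tubule of the maturing pronephric kidney.",
    is_a = id(2), part_of = id(5), start = 37, end = 64))
  doc <- add(doc, .anat_term(id(9), "pronephric duct",
    "Duct draining the pronephric kidney to the cloaca.",
    is_a = id(2), part_of = id(5), start = 30, end = 56))
  doc <- add(doc, .anat_term(id(10), "nephrostome",
    "Ciliated opening connecting the coelom to a pronephric tubule.",
    is_a = id(2), part_of = id(5), start = 33, end = 56))
  doc <- add(doc, .anat_term(id(11), "tail region",
    "Posterior region of the embryo and tadpole, resorbed at metamorphosis.",
    is_a = id(2), start = 26, end = 66))
  doc <- add(doc, .anat_term(id(12), "mesonephric kidney",
    "Adult kidney of the frog.",
    is_a = id(2), develops_from = id(3), start = 39, end = DEATH,
    xrefs = "UBERON:0000080"))
  doc <- add(doc, .anat_term(id(13), "cardiac mesoderm",
    "Mesoderm fated to form the heart.",
    is_a = id(3), start = 13, end = 32))
  doc <- add(doc, .anat_term(id(14), "heart",
    "Muscular organ that pumps blood through the circulatory system.",
    is_a = id(2), develops_from = id(13), start = 33, end = DEATH,
    xrefs = "UBERON:0000948"))
  doc <- add(doc, .anat_term(id(15), "brain",
    "Anterior organ of the central nervous system.",
    is_a = id(2), start = 22, end = DEATH,
    xrefs = "UBERON:0000955"))
  doc <- add(doc, .anat_term(id(16), "forebrain",
    "Anterior of the three principal brain regions.",
    is_a = id(2), part_of = id(15), start = 24, end = DEATH))
  doc <- add(doc, .anat_term(id(17), "neural crest",
    "Migratory embryonic cell population arising at the neural plate border.",
    is_a = id(2), start = 12, end = 50,
    xrefs = "UBERON:0002342"))
  doc <- add(doc, .anat_term(id(18), "craniofacial skeleton",
    "Skeletal elements of the skull and face.",
    is_a = id(2), develops_from = id(17), start = 39, end = DEATH))
  doc <- add(doc, .anat_term(id(19), "enteric neurons",
    "Neurons of the enteric nervous system of the hindgut.",
    is_a = id(2), develops_from = id(17), start = 40, end = DEATH))
  doc
}

#' Generator parameters for random rule-conformant ontologies
#'
#' @param n_terms Number of anatomical terms, including the upper-level
#'   root and scaffold nodes (minimum 1).
#' @param max_is_a_parents Maximum number of is_a parents per term.
#' @param p_part_of,p_develops_from Per-term probabilities of carrying a
#'   partonomy / lineage assertion (when a timing-compatible target exists).
#' @param n_stages Length of the stage chain (default 66).
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   document exactly.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_terms = 50L, max_is_a_parents = 2L,
                             p_part_of = 0.3, p_develops_from = 0.2,
                             n_stages = 66L, seed = 1L) {
  stopifnot(n_terms >= 1L, max_is_a_parents >= 1L,
            p_part_of >= 0, p_part_of <= 1,
            p_develops_from >= 0, p_develops_from <= 1,
            n_stages >= 1L)
  structure(list(n_terms = as.integer(n_terms),
                 max_is_a_parents = as.integer(max_is_a_parents),
                 p_part_of = p_part_of, p_develops_from = p_develops_from,
                 n_stages = as.integer(n_stages), seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a random rule-conformant ontology
#'
#' Builds a stage chain plus a random anatomical is_a DAG in which every
#' validation rule holds by construction: intervals are assigned top-down
#' (each child's window sampled within the intersection of its parents'
#' windows), and partonomy / lineage edges are added only to
#' timing-compatible targets. All non-is_a edges point from newer to older
#' terms, so the combined subgraph is acyclic. An upper root (exempt from
#' R2/R7 by the default whitelist) and a scaffold node carrying `part_of`
#' and `develops_from` assertions guarantee relational completeness for
#' every descendant.
#'
#' @param params A [generator_params()].
#' @return An [obo_document()] that [validate()]s with zero violations.
#' @examples
#' doc <- generate_ontology(generator_params(n_terms = 10, seed = 42))
#' validate(build_graph(doc))$valid
#' @export
generate_ontology <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  n_stages <- params$n_stages
  .with_seed(params$seed, {
    doc <- nf_stage_chain(n_stages)
    n <- params$n_terms

    # ordinal bookkeeping for timing-compatible sampling
    si <- integer(0); ei <- integer(0); ids <- character(0)

    add <- function(doc, t) { doc$terms[[t$id]] <- t; doc }

    doc <- add(doc, .anat_term(.xaot_id(1), "anatomical entity",
      "Upper-level root class for anatomical entities.",
      start = 1, end = n_stages))
    ids <- .xaot_id(1); si <- 1L; ei <- n_stages

    if (n >= 2L) {
      doc <- add(doc, .anat_term(.xaot_id(2), "anatomical structure",
        "Material anatomical entity with inherent 3D shape.",
        is_a = .xaot_id(1), part_of = .xaot_id(1),
        develops_from = .xaot_id(1), start = 1, end = n_stages))
      ids <- c(ids, .xaot_id(2)); si <- c(si, 1L); ei <- c(ei, n_stages)
    }

    for (k in seq_len(max(0L, n - 2L)) + 2L) {
      # first parent from the non-root pool so everything descends from
      # the scaffold; extra parents only where the windows intersect
      pool <- 2:(k - 1L)
      # a fraction of terms found fresh top-level lineages (major systems
      # attach high in the classification, keeping the full stage range
      # available); the rest nest under an existing term
      p1 <- if (length(pool) == 1L || stats::runif(1) < 0.25) 2L else
        sample(pool, 1L)
      parents <- p1
      if (params$max_is_a_parents > 1L && length(pool) > 1L &&
          stats::runif(1) < 0.3) {
        compat <- setdiff(pool[si[pool] <= ei[p1] & ei[pool] >= si[p1]],
                          p1)
        if (length(compat))
          parents <- c(p1, if (length(compat) == 1L) compat else
            sample(compat, 1L))
      }
      lo <- max(si[parents]); hi <- min(ei[parents])
      if (lo > hi)
        stop("generation error: could not nest intervals; ",
             "n_stages too small for the requested structure",
             call. = FALSE)

      # window mix: subtypes spanning the parent window, short-lived
      # transient structures, and structures persisting to the parent
      # end; start stages are biased early, as most structures arise
      # during embryogenesis rather than late development
      early_start <- function() {
        lo + min(hi - lo, as.integer(floor((hi - lo + 1L) *
                                             stats::runif(1)^2)))
      }
      r <- stats::runif(1)
      if (r < 0.25) {               # same window as the parent(s)
        s <- lo; e <- hi
      } else if (r < 0.65) {        # transient: bounded window
        s <- early_start()
        e <- s + as.integer(floor((hi - s) * stats::runif(1) * 0.5))
      } else {                      # persists to the parent's end
        s <- early_start()
        e <- hi
      }

      part_of <- character(0)
      if (stats::runif(1) < params$p_part_of) {
        cand <- which(si <= s & ei >= e)
        if (length(cand))
          part_of <- ids[if (length(cand) == 1L) cand else
            sample(cand, 1L)]
      }
      develops_from <- character(0)
      if (stats::runif(1) < params$p_develops_from) {
        cand <- which(si <= s & (ei + 1L) >= s)
        if (length(cand))
          develops_from <- ids[if (length(cand) == 1L) cand else
            sample(cand, 1L)]
      }

      syn <- empty_synonyms()
      if (stats::runif(1) < 0.3)
        syn <- data.frame(label = sprintf("synonym of term %04d", k),
                          scope = sample(xao_synonym_scopes(), 1L),
                          stringsAsFactors = FALSE)
      xr <- if (stats::runif(1) < 0.3)
        sprintf("UBERON:%07d", sample.int(9999999L, 1L)) else character(0)

      doc <- add(doc, .anat_term(.xaot_id(k), sprintf("term %04d", k),
        sprintf("Generated anatomical term number %d.", k),
        is_a = ids[parents], part_of = part_of,
        develops_from = develops_from, start = s, end = e,
        synonyms = syn, xrefs = xr))
      ids <- c(ids, .xaot_id(k)); si <- c(si, s); ei <- c(ei, e)
    }
    doc
  })
}

# ---- violation injection -------------------------------------------------

.term_leaves <- function(graph, anat) {
  isa_parents <- unique(graph$edges$object[graph$edges$relation == "is_a"])
  setdiff(anat, isa_parents)
}

.subjects_of <- function(graph, rels) {
  unique(graph$edges$subject[graph$edges$relation %in% rels])
}
.objects_of <- function(graph, rels) {
  unique(graph$edges$object[graph$edges$relation %in% rels])
}

# remove one relationship row matching relation (and optionally target)
.drop_relationship <- function(term, relation, target = NULL) {
  r <- term$relationships
  hit <- which(r$relation == relation &
                 (is.null(target) | r$target == (target %||% "")))
  stopifnot(length(hit) >= 1L)
  term$relationships <- r[-hit[1], , drop = FALSE]
  rownames(term$relationships) <- NULL
  term
}

.add_relationship <- function(term, relation, target) {
  term$relationships <- rbind(
    term$relationships,
    data.frame(relation = relation, target = target,
               stringsAsFactors = FALSE))
  rownames(term$relationships) <- NULL
  term
}

# replace a term's stage window (ordinals resolved against the series)
.retime_term <- function(term, series, s_ord, e_ord) {
  term <- .drop_relationship(term, "starts_during")
  term <- .drop_relationship(term, "ends_during")
  term <- .add_relationship(term, "starts_during", series$ids[s_ord])
  .add_relationship(term, "ends_during", series$ids[e_ord])
}

# leaves that nothing else references: no is_a children, no incoming or
# outgoing part_of/develops_from -- retiming them is collateral-free
.safe_leaves <- function(graph, leaves, tsub, tobj) {
  setdiff(leaves, c(tsub, tobj))
}

#' Inject targeted rule violations into a clean ontology
#'
#' Applies seeded, targeted mutations to a document that validates clean,
#' one per requested violation, and records each mutation in a ledger. The
#' mutations are chosen so that each one trips exactly its own rule:
#' [validate()] on the returned document reports exactly the ledger
#' entries (same rule codes and subjects) and nothing else.
#'
#' @param doc A clean [obo_document()] (e.g. from [generate_ontology()]).
#' @param spec Named integer vector mapping rule codes to requested
#'   violation counts, e.g. `c(R1 = 1, R5 = 2)`.
#' @param seed Integer seed controlling mutation choices.
#' @return A list with `doc` (the mutated document) and `ledger` (data
#'   frame with columns `rule`, `subject`, `description`).
#' @export
inject_violations <- function(doc, spec, seed = 1L) {
  stopifnot(length(spec) > 0L, !is.null(names(spec)))
  bad <- setdiff(names(spec), .RULE_CODES)
  if (length(bad))
    stop("unknown rule code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  ledger <- data.frame(rule = character(), subject = character(),
                       description = character(), stringsAsFactors = FALSE)
  used <- character(0)   # terms already involved in a mutation

  .with_seed(seed, {
    for (code in intersect(.RULE_CODES, names(spec))) {
      for (rep in seq_len(spec[[code]])) {
        graph <- build_graph(doc)
        series <- build_stage_series(graph)
        n_stages <- length(series$ids)
        anat <- setdiff(names(graph$terms), series$ids)
        roots <- unique(c(
          intersect("anatomical entity", names(graph$terms)),
          unlist(graph$name_index[["anatomical entity"]],
                 use.names = FALSE)))
        scaffold <- unlist(graph$name_index[["anatomical structure"]],
                           use.names = FALSE)
        protected <- unique(c(roots, scaffold, used))
        leaves <- setdiff(.term_leaves(graph, anat), protected)
        timing <- .term_timing(graph, series, anat)
        tsub <- .subjects_of(graph, c("part_of", "develops_from"))
        tobj <- .objects_of(graph, c("part_of", "develops_from"))
        pick <- function(cand, rule) {
          cand <- setdiff(cand, protected)
          if (!length(cand))
            stop("cannot realize requested violation for rule ", rule,
                 ": no eligible mutation site", call. = FALSE)
          if (length(cand) == 1L) cand else sample(cand, 1L)
        }

        if (code == "R1") {
          id <- pick(setdiff(anat, roots), "R1")
          doc$terms[[id]]$def <- NA_character_
          doc$terms[[id]]$def_xrefs <- character(0)
          ledger <- rbind(ledger, data.frame(
            rule = "R1", subject = id,
            description = paste("removed definition of", id),
            stringsAsFactors = FALSE))
          used <- c(used, id)

        } else if (code == "R2") {
          id <- pick(leaves[vapply(leaves, function(l)
            length(doc$terms[[l]]$is_a) > 0, logical(1))], "R2")
          # keep R7 satisfied for the orphan via its own assertions
          rels <- doc$terms[[id]]$relationships$relation
          if (!("part_of" %in% rels))
            doc$terms[[id]] <- .add_relationship(doc$terms[[id]],
                                                 "part_of", roots[1])
          if (!("develops_from" %in% rels))
            doc$terms[[id]] <- .add_relationship(doc$terms[[id]],
                                                 "develops_from", roots[1])
          doc$terms[[id]]$is_a <- character(0)
          ledger <- rbind(ledger, data.frame(
            rule = "R2", subject = id,
            description = paste("removed all is_a parents of", id),
            stringsAsFactors = FALSE))
          used <- c(used, id)

        } else if (code == "R3") {
          # breaking a term's timing only SKIPS checks that involve it,
          # and the document was clean, so no collateral findings appear
          id <- pick(setdiff(anat, roots), "R3")
          doc$terms[[id]] <- .drop_relationship(doc$terms[[id]],
                                                "starts_during")
          ledger <- rbind(ledger, data.frame(
            rule = "R3", subject = id,
            description = paste("removed starts_during of", id),
            stringsAsFactors = FALSE))
          used <- c(used, id)

        } else if (code == "R4") {
          # widen a leaf's window past exactly one parent's bound; only
          # leaves with no outgoing part_of/develops_from are safe
          sites <- list()
          for (l in setdiff(leaves, tsub)) {
            t <- doc$terms[[l]]
            ps <- t$is_a
            if (!length(ps) || !isTRUE(timing[[l]]$ok)) next
            if (!all(vapply(ps, function(p)
              isTRUE(timing[[p]]$ok), logical(1)))) next
            for (p in ps) {
              others <- setdiff(ps, p)
              o_hi <- if (length(others))
                min(vapply(others, function(q) timing[[q]]$ei,
                           integer(1))) else n_stages
              o_lo <- if (length(others))
                max(vapply(others, function(q) timing[[q]]$si,
                           integer(1))) else 1L
              if (timing[[p]]$ei < n_stages && timing[[p]]$ei + 1L <= o_hi)
                sites[[length(sites) + 1L]] <-
                  list(id = l, parent = p, ord = timing[[p]]$ei + 1L,
                       side = "end")
              if (timing[[p]]$si > 1L && timing[[p]]$si - 1L >= o_lo)
                sites[[length(sites) + 1L]] <-
                  list(id = l, parent = p, ord = timing[[p]]$si - 1L,
                       side = "start")
            }
          }
          sites <- Filter(function(s) !(s$id %in% protected) &&
                            !(s$parent %in% protected), sites)
          if (!length(sites))
            stop("cannot realize requested violation for rule R4",
                 call. = FALSE)
          s4 <- sites[[sample.int(length(sites), 1L)]]
          rel <- if (s4$side == "end") "ends_during" else "starts_during"
          doc$terms[[s4$id]] <- .drop_relationship(doc$terms[[s4$id]], rel)
          doc$terms[[s4$id]] <- .add_relationship(doc$terms[[s4$id]], rel,
                                                  series$ids[s4$ord])
          ledger <- rbind(ledger, data.frame(
            rule = "R4", subject = paste(s4$id, "is_a", s4$parent),
            description = paste("widened window of", s4$id,
                                "past its is_a parent", s4$parent),
            stringsAsFactors = FALSE))
          used <- c(used, s4$id, s4$parent)

        } else if (code == "R5") {
          pair <- .incompatible_pair(graph, timing, anat, protected,
                                     mode = "after", n_stages)
          if (is.null(pair)) {
            forged <- .forge_pair(doc, graph, series, timing, leaves,
                                  tsub, tobj, protected, anat, "after")
            if (!is.null(forged)) { doc <- forged$doc; pair <- forged$pair }
          }
          if (is.null(pair))
            stop("cannot realize requested violation for rule R5",
                 call. = FALSE)
          doc$terms[[pair[1]]] <- .add_relationship(doc$terms[[pair[1]]],
                                                    "develops_from", pair[2])
          ledger <- rbind(ledger, data.frame(
            rule = "R5",
            subject = paste(pair[1], "develops_from", pair[2]),
            description = paste("added timing-incompatible develops_from",
                                "edge", pair[1], "->", pair[2]),
            stringsAsFactors = FALSE))
          used <- c(used, pair)

        } else if (code == "R6") {
          pair <- .incompatible_pair(graph, timing, anat, protected,
                                     mode = "outside", n_stages)
          if (is.null(pair)) {
            forged <- .forge_pair(doc, graph, series, timing, leaves,
                                  tsub, tobj, protected, anat, "outside")
            if (!is.null(forged)) { doc <- forged$doc; pair <- forged$pair }
          }
          if (is.null(pair))
            stop("cannot realize requested violation for rule R6",
                 call. = FALSE)
          doc$terms[[pair[1]]] <- .add_relationship(doc$terms[[pair[1]]],
                                                    "part_of", pair[2])
          ledger <- rbind(ledger, data.frame(
            rule = "R6", subject = paste(pair[1], "part_of", pair[2]),
            description = paste("added non-contained part_of edge",
                                pair[1], "->", pair[2]),
            stringsAsFactors = FALSE))
          used <- c(used, pair)

        } else if (code == "R7") {
          # cut a leaf off from the part_of/develops_from-bearing part of
          # its ancestry by reparenting it directly under the exempt root
          cand <- Filter(function(l) {
            t <- doc$terms[[l]]
            length(t$is_a) >= 1L &&
              !any(t$relationships$relation %in%
                     c("part_of", "develops_from"))
          }, leaves)
          id <- pick(unlist(cand) %||chr% character(), "R7")
          doc$terms[[id]]$is_a <- roots[1]
          ledger <- rbind(ledger, data.frame(
            rule = "R7", subject = id,
            description = paste("reparented", id, "directly under the",
                                "root, away from the part_of/",
                                "develops_from-bearing scaffold"),
            stringsAsFactors = FALSE))
          used <- c(used, id)

        } else if (code == "R8") {
          id <- pick(anat, "R8")
          target <- paste0(.XAOT_PREFIX, ":9999999")
          doc$terms[[id]] <- .add_relationship(doc$terms[[id]],
                                               "part_of", target)
          ledger <- rbind(ledger, data.frame(
            rule = "R8", subject = paste(id, "part_of", target),
            description = paste("added dangling part_of edge from", id),
            stringsAsFactors = FALSE))
          used <- c(used, id)

        } else if (code == "R9") {
          e <- graph$active_edges
          isa <- e[e$relation == "is_a" & e$subject %in% anat &
                     e$object %in% anat, , drop = FALSE]
          ok <- vapply(seq_len(nrow(isa)), function(k) {
            ch <- timing[[isa$subject[k]]]; pa <- timing[[isa$object[k]]]
            tch <- doc$terms[[isa$subject[k]]]
            # the child's single outgoing edge must be this is_a, so the
            # created cycle is exactly the 2-cycle in the ledger
            !is.null(ch) && !is.null(pa) && ch$ok && pa$ok &&
              ch$si == pa$si && ch$ei == pa$ei &&
              length(tch$is_a) == 1L &&
              !any(tch$relationships$relation %in%
                     c("part_of", "develops_from")) &&
              !(isa$subject[k] %in% protected) &&
              !(isa$object[k] %in% c(protected, roots))
          }, logical(1))
          isa <- isa[ok, , drop = FALSE]
          if (nrow(isa)) {
            k <- if (nrow(isa) == 1L) 1L else sample.int(nrow(isa), 1L)
            ch <- isa$subject[k]; pa <- isa$object[k]
          } else {
            # manufacture a site: copy the parent's window onto an
            # unreferenced single-parent leaf (a subtype spanning its
            # parent's window is valid), then add the reverse edge
            safe <- setdiff(.safe_leaves(graph, leaves, tsub, tobj),
                            protected)
            safe <- safe[vapply(safe, function(l) {
              t <- doc$terms[[l]]
              length(t$is_a) == 1L && isTRUE(timing[[l]]$ok) &&
                isTRUE(timing[[t$is_a]]$ok) && !(t$is_a %in% roots)
            }, logical(1))]
            if (!length(safe))
              stop("cannot realize requested violation for rule R9",
                   call. = FALSE)
            ch <- if (length(safe) == 1L) safe else sample(safe, 1L)
            pa <- doc$terms[[ch]]$is_a
            doc$terms[[ch]] <- .retime_term(doc$terms[[ch]], series,
                                            timing[[pa]]$si,
                                            timing[[pa]]$ei)
          }
          doc$terms[[pa]]$is_a <- c(doc$terms[[pa]]$is_a, ch)
          ledger <- rbind(ledger, data.frame(
            rule = "R9", subject = paste(sort(c(ch, pa)), collapse = ","),
            description = paste("added reverse is_a edge", pa, "->", ch,
                                "creating a 2-cycle"),
            stringsAsFactors = FALSE))
          used <- c(used, ch, pa)

        } else if (code == "R10") {
          id <- pick(setdiff(anat, roots), "R10")
          doc$terms[[id]] <- .drop_relationship(doc$terms[[id]],
                                                "starts_during")
          doc$terms[[id]] <- .add_relationship(doc$terms[[id]],
                                               "starts_during", roots[1])
          ledger <- rbind(ledger, data.frame(
            rule = "R10", subject = paste(id, "starts_during", roots[1]),
            description = paste("retargeted starts_during of", id,
                                "to a non-stage term"),
            stringsAsFactors = FALSE))
          used <- c(used, id)
        }
      }
    }
  })
  list(doc = doc, ledger = ledger)
}

# manufacture a timing-incompatible (X, Y) pair when none exists: retime
# one (or two) unreferenced leaves within their parents' allowance --
# itself violation-free -- so that X's window is incompatible with Y's.
# X is a leaf nothing references, so the new X -> Y edge cannot close a
# cycle. Returns list(doc, pair) or NULL.
.forge_pair <- function(doc, graph, series, timing, leaves, tsub, tobj,
                        protected, anat, mode) {
  safe <- setdiff(.safe_leaves(graph, leaves, tsub, tobj), protected)
  safe <- safe[vapply(safe, function(l) {
    isTRUE(timing[[l]]$ok) &&
      all(vapply(doc$terms[[l]]$is_a, function(p)
        isTRUE(timing[[p]]$ok), logical(1))) &&
      length(doc$terms[[l]]$is_a) >= 1L
  }, logical(1))]
  bounds <- function(l) {
    ps <- doc$terms[[l]]$is_a
    c(max(vapply(ps, function(p) timing[[p]]$si, integer(1))),
      min(vapply(ps, function(p) timing[[p]]$ei, integer(1))))
  }
  for (l in if (length(safe)) sample(safe) else character(0)) {
    b <- bounds(l); plo <- b[1]; phi <- b[2]
    if (mode == "after") {
      # X sits at a late point window; Y must end at least 2 before it
      ys <- setdiff(anat, c(protected, l))
      ys <- ys[vapply(ys, function(y)
        isTRUE(timing[[y]]$ok) && timing[[y]]$ei + 1L < phi, logical(1))]
      if (length(ys)) {
        y <- if (length(ys) == 1L) ys else sample(ys, 1L)
        doc$terms[[l]] <- .retime_term(doc$terms[[l]], series, phi, phi)
        return(list(doc = doc, pair = c(l, y)))
      }
      for (m in setdiff(safe, l)) {
        bm <- bounds(m)
        if (bm[1] + 1L < phi) {
          doc$terms[[l]] <- .retime_term(doc$terms[[l]], series, phi, phi)
          doc$terms[[m]] <- .retime_term(doc$terms[[m]], series,
                                         bm[1], bm[1])
          return(list(doc = doc, pair = c(l, m)))
        }
      }
    } else {
      # X takes its widest allowed window; Y must not contain it
      ys <- setdiff(anat, c(protected, l))
      ys <- ys[vapply(ys, function(y)
        isTRUE(timing[[y]]$ok) &&
          (plo < timing[[y]]$si || phi > timing[[y]]$ei), logical(1))]
      if (length(ys)) {
        y <- if (length(ys) == 1L) ys else sample(ys, 1L)
        doc$terms[[l]] <- .retime_term(doc$terms[[l]], series, plo, phi)
        return(list(doc = doc, pair = c(l, y)))
      }
      for (m in setdiff(safe, l)) {
        bm <- bounds(m)
        if (bm[1] > plo || bm[1] < phi) {
          doc$terms[[l]] <- .retime_term(doc$terms[[l]], series, plo, phi)
          doc$terms[[m]] <- .retime_term(doc$terms[[m]], series,
                                         bm[1], bm[1])
          return(list(doc = doc, pair = c(l, m)))
        }
      }
    }
  }
  NULL
}

# find (X, Y) where adding X -> Y creates no cycle and X's window is
# "after": starts more than one stage past Y's end (trips R5)
# "outside": not contained in Y's window (trips R6)
.incompatible_pair <- function(graph, timing, anat, protected, mode,
                               n_stages) {
  cand <- setdiff(anat, protected)
  cand <- cand[vapply(cand, function(i) isTRUE(timing[[i]]$ok), logical(1))]
  if (length(cand) < 2L) return(NULL)
  pairs <- expand.grid(x = cand, y = cand, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, , drop = FALSE]
  xs <- vapply(pairs$x, function(i) timing[[i]]$si, integer(1))
  xe <- vapply(pairs$x, function(i) timing[[i]]$ei, integer(1))
  ys <- vapply(pairs$y, function(i) timing[[i]]$si, integer(1))
  ye <- vapply(pairs$y, function(i) timing[[i]]$ei, integer(1))
  hit <- if (mode == "after") xs > ye + 1L else (xs < ys | xe > ye)
  pairs <- pairs[hit, , drop = FALSE]
  if (!nrow(pairs)) return(NULL)
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  ex <- graph$edges
  for (k in seq_len(nrow(pairs))) {
    x <- pairs$x[k]; y <- pairs$y[k]
    if (any(ex$subject == x & ex$object == y)) next
    if (x %in% .reach(graph$adj_up, c("is_a", "part_of", "develops_from"),
                      y)) next
    return(c(x, y))
  }
  NULL
}

# ---- annotation corpus ---------------------------------------------------

#' Generate an expression-annotation corpus with a validity ledger
#'
#' Samples `(gene, term, stage, record)` tuples from the anatomical terms
#' of `doc`. Valid rows draw their stage uniformly from the term's own
#' existence window; invalid rows draw a stage strictly outside it (only
#' terms whose window does not cover the whole chain can host an invalid
#' row).
#'
#' @param doc An [obo_document()].
#' @param n_records Number of annotation rows.
#' @param p_invalid Probability that a row is deliberately out of window.
#' @param seed Integer seed.
#' @return A list with `annotations` (data frame with columns `gene`,
#'   `term_id`, `stage_id`, `record_id`) and `ledger` (logical vector,
#'   `TRUE` for rows constructed to be valid).
#' @export
generate_corpus <- function(doc, n_records = 100L, p_invalid = 0,
                            seed = 1L) {
  graph <- build_graph(doc)
  series <- build_stage_series(graph)
  anat <- setdiff(names(graph$terms), series$ids)
  timing <- .term_timing(graph, series, anat)
  ok <- anat[vapply(anat, function(i) isTRUE(timing[[i]]$ok), logical(1))]
  n_stages <- length(series$ids)
  shrinkable <- ok[vapply(ok, function(i)
    timing[[i]]$si > 1L || timing[[i]]$ei < n_stages, logical(1))]
  if (!length(ok))
    stop("no terms with resolvable windows to annotate", call. = FALSE)
  if (p_invalid > 0 && !length(shrinkable))
    stop("no term window leaves room for an invalid stage", call. = FALSE)

  .with_seed(seed, {
    valid <- stats::runif(n_records) >= p_invalid
    gene <- sprintf("gene%04d", sample.int(9999L, n_records, replace = TRUE))
    term <- character(n_records); stage <- character(n_records)
    for (r in seq_len(n_records)) {
      if (valid[r]) {
        t <- if (length(ok) == 1L) ok else sample(ok, 1L)
        w <- timing[[t]]
        s <- if (w$si == w$ei) w$si else sample(w$si:w$ei, 1L)
      } else {
        t <- if (length(shrinkable) == 1L) shrinkable else
          sample(shrinkable, 1L)
        w <- timing[[t]]
        outside <- setdiff(seq_len(n_stages), w$si:w$ei)
        s <- if (length(outside) == 1L) outside else sample(outside, 1L)
      }
      term[r] <- t
      stage[r] <- series$ids[s]
    }
    list(annotations = data.frame(
      gene = gene, term_id = term, stage_id = stage,
      record_id = sprintf("XB-IMG-%04d", seq_len(n_records)),
      stringsAsFactors = FALSE),
      ledger = valid)
  })
}
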