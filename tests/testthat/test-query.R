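test_that("search returns the exact match first and relational neighbors", {
  res <- search_terms(fig2_graph, "heart", include_related = TRUE)
  expect_equal(res$name[1], "heart")
  expect_equal(res$kind[1], "exact_name")
  cm <- res[res$name == "cardiac mesoderm", ]
  expect_equal(cm$kind, "related")
})

test_that("synonyms are searchable in every mode", {
  res <- search_terms(fig2_graph, "pronephros", match_mode = "exact")
  expect_equal(res$name, "pronephric kidney")
  expect_equal(res$kind, "exact_synonym")
})

test_that("search is case-insensitive and respects match modes", {
  expect_identical(search_terms(fig2_graph, "HEART"),
                   search_terms(fig2_graph, "heart"))
  doc <- generate_ontology(generator_params(n_terms = 15, seed = 8))
  g <- build_graph(doc)
  expect_identical(search_terms(g, "TERM 0007"), search_terms(g, "term 0007"))

  pron <- search_terms(fig2_graph, "pronephric", match_mode = "prefix")
  expect_true(all(startsWith(tolower(pron$matched_label), "pronephric")))
  sub <- search_terms(fig2_graph, "kidney", match_mode = "substring")
  expect_true(fid("mesonephric kidney") %in% sub$id)
  expect_length(search_terms(fig2_graph, "kidney",
                             match_mode = "exact")$id, 0L)
  expect_error(search_terms(fig2_graph, "   "), "empty query")
})

test_that("ranking orders exact name over synonym over prefix, ties by name", {
  doc <- obo_document(terms = list(
    obo_term("XAOT:0000003", name = "eyelid"),
    obo_term("XAOT:0000002", name = "optic cup",
             synonyms = data.frame(label = "eye", scope = "EXACT",
                                   stringsAsFactors = FALSE)),
    obo_term("XAOT:0000001", name = "eye")))
  res <- search_terms(build_graph(doc), "eye")
  expect_equal(res$kind, c("exact_name", "exact_synonym", "prefix"))
  expect_equal(res$id, c("XAOT:0000001", "XAOT:0000002", "XAOT:0000003"))
})

test_that("successor expansion reaches all neural crest derivatives", {
  ids <- expand_term(fig2_graph, fid("neural crest"),
                     query_options(include_successors = TRUE))
  expect_true(all(c(fid("craniofacial skeleton"), fid("enteric neurons"))
                  %in% ids))
  expect_false(fid("heart") %in% ids)
})

test_that("expansion with every option off is the term itself", {
  opts <- query_options(include_subtypes = FALSE)
  expect_equal(expand_term(fig2_graph, fid("pronephric kidney"), opts),
               fid("pronephric kidney"))
})

test_that("expansion equals brute-force reachability and is monotone", {
  combos <- list(
    query_options(),
    query_options(include_parts = TRUE),
    query_options(include_parts = TRUE, include_successors = TRUE),
    query_options(include_parts = TRUE, include_successors = TRUE,
                  include_precursors = TRUE))
  for (seed in 1:10) {
    doc <- generate_ontology(generator_params(n_terms = 25, seed = seed,
                                              n_stages = 25))
    g <- build_graph(doc)
    s <- build_stage_series(g)
    anat <- setdiff(names(g$terms), s$ids)
    for (id in anat[c(4, 12, 20)]) {
      prev <- NULL
      for (opts in combos) {
        got <- expand_term(g, id, opts)
        expect_setequal(got, bf_expand(g, id, opts))
        if (!is.null(prev)) expect_true(all(prev %in% got))
        prev <- got
      }
    }
  }
})

test_that("stage filtering keeps terms whose window touches the range", {
  kid <- fid("pronephric kidney")
  expect_equal(
    as.character(filter_by_stage(fig2_graph, fig2_series, kid,
                                 c("NF stage 30", "NF stage 30"))), kid)
  # inclusive at the exact start boundary
  expect_equal(
    as.character(filter_by_stage(fig2_graph, fig2_series, kid,
                                 c("NF stage 28", "NF stage 28"))), kid)
  expect_length(filter_by_stage(fig2_graph, fig2_series, kid,
                                c("NF stage 1", "NF stage 27")), 0L)

  # agreement with per-stage enumeration over all terms and single stages
  anat <- setdiff(names(fig2_graph$terms), fig2_series$ids)
  for (ord in c(1, 25, 28, 40, 67)) {
    stage <- fig2_series$ids[ord]
    kept <- filter_by_stage(fig2_graph, fig2_series, anat,
                            c(stage, stage))
    manual <- anat[vapply(anat, function(i) {
      iv <- interval_of(fig2_graph, fig2_series, i)
      ord %in% seq(stage_index(fig2_series, iv$start),
                   stage_index(fig2_series, iv$end))
    }, logical(1))]
    expect_setequal(as.character(kept), manual)
  }
})

test_that("ontology-expanded retrieval finds part-annotated records", {
  corpus <- data.frame(
    gene = c("slc12a1", "slc5a1.2", "pax2", "nkx2-5"),
    term_id = c(fid("early distal tubule"), fid("pronephric duct"),
                fid("nephrostome"), fid("heart")),
    stage_id = c("NF stage 37", "NF stage 33", "NF stage 35", "NF stage 40"),
    record_id = paste0("XB-IMG-", 1:4),
    stringsAsFactors = FALSE)
  hits <- retrieve_annotations(fig2_graph, fig2_series, corpus,
                               "pronephric kidney",
                               query_options(include_parts = TRUE))
  expect_setequal(hits$gene, c("slc12a1", "slc5a1.2", "pax2"))
  exact <- retrieve_annotations(fig2_graph, fig2_series, corpus,
                                "pronephric kidney",
                                query_options(include_subtypes = FALSE))
  expect_equal(nrow(exact), 0L)
  expect_true(all(exact$record_id %in% hits$record_id))
})

test_that("unresolvable corpus rows are reported, never dropped silently", {
  corpus <- data.frame(gene = "gdf1", term_id = "XAOT:5555555",
                       stage_id = "NF stage 10", record_id = "XB-IMG-9",
                       stringsAsFactors = FALSE)
  hits <- retrieve_annotations(fig2_graph, fig2_series, corpus,
                               "pronephric kidney")
  expect_equal(nrow(hits), 0L)
  expect_equal(attr(hits, "unresolved")$record_id, "XB-IMG-9")
})

test_that("retrieved records equal a brute-force corpus scan", {
  for (seed in c(3, 7)) {
    doc <- generate_ontology(generator_params(n_terms = 30, seed = seed))
    corp <- generate_corpus(doc, n_records = 60, p_invalid = 0.2,
                            seed = seed)$annotations
    g <- build_graph(doc)
    s <- build_stage_series(g)
    anat <- setdiff(names(g$terms), s$ids)
    opts <- query_options(include_parts = TRUE, include_successors = TRUE)
    for (id in anat[c(5, 15)]) {
      hits <- retrieve_annotations(g, s, corp, id, opts)
      manual <- corp[corp$term_id %in% expand_term(g, id, opts), ]
      expect_setequal(hits$record_id, manual$record_id)
    }
  }
})

test_that("stage-restricted annotation checking is inclusive on both ends", {
  g <- fig2_graph; s <- fig2_series
  expect_true(check_annotation(g, s, "early distal tubule",
                               "NF stage 37/38", gene = "slc12a1")$valid)
  expect_true(check_annotation(g, s, "late proximal tubule",
                               "NF stage 37/38", gene = "slc5a1.2")$valid)
  expect_false(check_annotation(g, s, "pronephric kidney",
                                "NF stage 10")$valid)
  expect_true(check_annotation(g, s, "pronephric kidney",
                               "NF stage 28")$valid)   # exact start
  expect_true(check_annotation(g, s, "pronephric kidney",
                               "NF stage 64")$valid)   # exact end
  expect_false(check_annotation(g, s, "pronephric kidney",
                                "NF stage 65")$valid)
  # a range is valid only when wholly inside the window
  expect_true(check_annotation(g, s, "pronephric kidney",
                               "NF stage 30..NF stage 40")$valid)
  expect_false(check_annotation(g, s, "pronephric kidney",
                                "NF stage 27..NF stage 40")$valid)
  # resolution failures are errors, not invalid verdicts
  expect_error(check_annotation(g, s, "no such term", "NF stage 10"),
               "not found")
  expect_error(check_annotation(g, s, "heart", "NF stage 999"),
               "does not resolve")
})

test_that("generated corpora behave per their validity ledger", {
  doc <- generate_ontology(generator_params(n_terms = 25, seed = 13))
  g <- build_graph(doc)
  s <- build_stage_series(g)
  all_valid <- generate_corpus(doc, 40, p_invalid = 0, seed = 2)
  res <- check_corpus(g, s, all_valid$annotations)
  expect_true(all(res$status == "valid"))

  none_valid <- generate_corpus(doc, 40, p_invalid = 1, seed = 2)
  res2 <- check_corpus(g, s, none_valid$annotations)
  expect_true(all(res2$status == "invalid"))

  mixed <- generate_corpus(doc, 40, p_invalid = 0.4, seed = 5)
  res3 <- check_corpus(g, s, mixed$annotations)
  expect_identical(res3$status == "valid", mixed$ledger)
  expect_identical(generate_corpus(doc, 40, p_invalid = 0.4, seed = 5),
                   mixed)
})

test_that("annotation corpora round-trip through the TSV format", {
  corp <- generate_corpus(fig2_doc, 12, p_invalid = 0.5, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_annotations(corp$annotations, path)
  back <- read_annotations(path)
  expect_identical(back, corp$annotations)
  expect_error(read_annotations({
    p <- tempfile(); writeLines("a\tb", p); p
  }), "must have columns")
})
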