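test_that("an empty ontology summarizes to all zeros", {
  g <- build_graph(obo_document())
  st <- summarize_ontology(g)
  expect_equal(st$total_terms, 0L)
  expect_equal(st$anatomical_entities, 0L)
  expect_equal(st$developmental_stages, 0L)
  expect_equal(st$relationships_total, 0L)
  expect_equal(unname(st$per_relation), rep(0L, 6L))
  expect_equal(st$xrefs, 0L)
})

test_that("worked-example counts equal a direct stanza recount", {
  st <- summarize_ontology(fig2_graph, fig2_series)
  tally <- function(f) sum(vapply(fig2_doc$terms, f, integer(1)))
  expect_equal(st$total_terms, length(fig2_doc$terms))
  expect_equal(st$developmental_stages, 67L)  # 66 NF stages + sentinel
  expect_equal(st$anatomical_entities, st$total_terms - 67L)
  expect_equal(st$definitions, st$total_terms)  # definition-complete
  expect_equal(st$synonyms, tally(function(t) nrow(t$synonyms)))
  expect_equal(st$xrefs, tally(function(t) length(t$xrefs)))
  expect_equal(unname(st$per_relation["is_a"]),
               tally(function(t) length(t$is_a)))
  for (r in c("part_of", "develops_from", "starts_during", "ends_during",
              "preceded_by"))
    expect_equal(unname(st$per_relation[r]),
                 tally(function(t) sum(t$relationships$relation == r)))
  expect_equal(st$relationships_total, sum(st$per_relation))
})

test_that("summary identities hold on generated ontologies", {
  for (seed in c(1, 6, 21)) {
    p <- generator_params(n_terms = 30, seed = seed)
    doc <- generate_ontology(p)
    g <- build_graph(doc)
    s <- build_stage_series(g)
    st <- summarize_ontology(g, s)
    expect_equal(st$total_terms, p$n_terms + p$n_stages)
    expect_equal(st$total_terms,
                 st$anatomical_entities + st$developmental_stages)
    expect_equal(st$relationships_total, sum(st$per_relation))
    expect_lte(st$definitions, st$total_terms)
  }
})

test_that("obsolete stanzas are excluded from summaries by default", {
  doc <- fig2_doc
  doc$terms[["XAOT:0000099"]] <- obo_term("XAOT:0000099", name = "retired",
                                          is_obsolete = TRUE)
  st <- summarize_ontology(build_graph(doc))
  expect_equal(st$total_terms, length(fig2_doc$terms))
})

test_that("a document diffed against itself is empty", {
  d <- diff_releases(fig2_doc, fig2_doc)
  expect_true(diff_is_empty(d))
})

test_that("scripted additions are recovered exactly, and diff is symmetric", {
  old <- generate_ontology(generator_params(n_terms = 20, seed = 17))
  new <- old

  added_term <- obo_term("XAOT:0000500", name = "novel structure",
                         def = "A newly described structure.",
                         is_a = "XAOT:0000002")
  new$terms[[added_term$id]] <- added_term

  t <- new$terms[["XAOT:0000005"]]
  t$synonyms <- rbind(t$synonyms, data.frame(
    label = "fresh synonym", scope = "EXACT", stringsAsFactors = FALSE))
  t$xrefs <- c(t$xrefs, "UBERON:0099999")
  t$relationships <- rbind(t$relationships, data.frame(
    relation = "part_of", target = "XAOT:0000500",
    stringsAsFactors = FALSE))
  t$def <- "A reworded definition."
  new$terms[[t$id]] <- t

  d <- diff_releases(old, new)
  expect_equal(d$terms_added, "XAOT:0000500")
  expect_length(d$terms_removed, 0L)
  expect_setequal(d$relationships_added,
                  c("XAOT:0000500 is_a XAOT:0000002",
                    "XAOT:0000005 part_of XAOT:0000500"))
  expect_equal(d$synonyms_added,
               "XAOT:0000005\tfresh synonym\tEXACT")
  expect_equal(d$xrefs_added, "XAOT:0000005\tUBERON:0099999")
  expect_equal(d$definitions_changed, "XAOT:0000005")

  back <- diff_releases(new, old)
  expect_identical(back$terms_added, d$terms_removed)
  expect_identical(back$terms_removed, d$terms_added)
  expect_identical(back$relationships_added, d$relationships_removed)
  expect_identical(back$relationships_removed, d$relationships_added)
  expect_identical(back$definitions_changed, d$definitions_changed)
})

test_that("report formatters emit parseable TSV and JSON", {
  st <- summarize_ontology(fig2_graph, fig2_series)
  tsv <- format_stats(st, "tsv")
  parsed <- utils::read.delim(text = tsv)
  expect_equal(parsed$count[parsed$metric == "total_terms"],
               st$total_terms)
  js <- jsonlite::fromJSON(format_stats(st, "json"))
  expect_equal(js$part_of, unname(st$per_relation[["part_of"]]))

  rep <- validate(fig2_graph, fig2_series)
  expect_equal(format_report(rep, "tsv"),
               "rule\tseverity\tsubject\tmessage")
  expect_true(jsonlite::fromJSON(format_report(rep, "json"))$valid)
})
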