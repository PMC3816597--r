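test_that("parsing a minimal term stanza yields the labelled term", {
  doc <- parse_obo(c("format-version: 1.2", "", "[Term]",
                     "id: XAO:0000010", "name: brain"))
  expect_length(doc$terms, 1L)
  expect_equal(doc$terms[["XAO:0000010"]]$name, "brain")
})

test_that("a header-only file parses to a document with no stanzas", {
  doc <- parse_obo("format-version: 1.2")
  expect_length(doc$terms, 0L)
  expect_equal(doc$header, "format-version: 1.2")
})

test_that("structured tags are parsed into fields and comments stripped", {
  doc <- parse_obo(c(
    "format-version: 1.2", "",
    "[Term]",
    "id: XAO:0000001",
    "name: pronephric kidney ! embryonic kidney",
    "namespace: xenopus_anatomy",
    "def: \"The embryonic kidney; a \\\"transient\\\" organ.\" [XB:curator, PMID:123]",
    "synonym: \"pronephros\" EXACT []",
    "xref: UBERON:0002120 \"pronephros\"",
    "is_a: XAO:0000002 ! kidney",
    "relationship: starts_during XAO:1000028",
    "alt_id: XAO:0009999"))
  t <- doc$terms[["XAO:0000001"]]
  expect_equal(t$name, "pronephric kidney")
  expect_equal(t$def, "The embryonic kidney; a \"transient\" organ.")
  expect_equal(t$def_xrefs, c("XB:curator", "PMID:123"))
  expect_equal(t$synonyms$label, "pronephros")
  expect_equal(t$synonyms$scope, "EXACT")
  expect_equal(t$xrefs, "UBERON:0002120")
  expect_equal(t$is_a, "XAO:0000002")
  expect_equal(t$relationships$relation, "starts_during")
  expect_equal(t$other, "alt_id: XAO:0009999")
})

test_that("malformed input is rejected with informative errors", {
  expect_error(parse_obo(c("format-version: 1.2", "[Term]", "id: A:1",
                           "[Term]", "id: A:1")), "duplicate term id")
  expect_error(parse_obo(c("format-version: 1.2", "[Frobnicate]")),
               "unreadable stanza header")
  expect_error(parse_obo(c("is_a: A:1", "[Term]", "id: A:1")),
               "not a header tag")
  expect_error(parse_obo(c("format-version: 1.2", "[Term]", "name: x")),
               "without id")
  expect_error(parse_obo(c("format-version: 1.2", "[Term]", "id: A:1",
                           "def: \"unterminated")), "unterminated")
  expect_error(parse_obo(c("format-version: 1.2", "[Term]", "id: A:1",
                           "synonym: \"x\" BOGUS []")), "synonym scope")
  expect_error(parse_obo(c("format-version: 1.2", "[Term]", "id: A:1",
                           "relationship: made_up A:2")),
               "undeclared relation")
})

test_that("writing uses canonical tag order and serialization checks ids", {
  t <- obo_term("XAOT:0000001", name = "heart",
                def = "A muscular organ.",
                is_a = "XAOT:0000002",
                xrefs = "UBERON:0000948")
  doc <- obo_document(terms = list(t))
  txt <- write_obo(doc)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(lines[1], "format-version: 1.2")
  stanza <- lines[(which(lines == "[Term]") + 1):length(lines)]
  expect_equal(stanza,
               c("id: XAOT:0000001", "name: heart",
                 "def: \"A muscular organ.\" []",
                 "xref: UBERON:0000948", "is_a: XAOT:0000002"))
  bad <- doc
  bad$terms[[1]]$id <- ""
  expect_error(write_obo(bad), "missing id")
})

test_that("parse-write round trip is the identity on fixture documents", {
  docs <- list(fig2_doc, nf_stage_chain(5),
               generate_ontology(generator_params(n_terms = 25, seed = 3)))
  for (doc in docs) {
    txt <- write_obo(doc)
    expect_true(obo_identical(doc, parse_obo(strsplit(txt, "\n")[[1]])))
  }
})

test_that("serialization is deterministic", {
  doc <- generate_ontology(generator_params(n_terms = 20, seed = 9))
  expect_identical(write_obo(doc), write_obo(doc))
  expect_identical(
    write_obo(generate_ontology(generator_params(n_terms = 20, seed = 9))),
    write_obo(doc))
})

test_that("escaped characters survive a round trip", {
  t <- obo_term("XAOT:0000001", name = "weird \"name\" with ! bang",
                def = "Has a backslash \\ and a \"quote\".")
  doc <- obo_document(terms = list(t))
  doc2 <- parse_obo(strsplit(write_obo(doc), "\n")[[1]])
  expect_equal(doc2$terms[[1]]$name, t$name)
  expect_equal(doc2$terms[[1]]$def, t$def)
})

test_that("an independent OBO reader agrees on the term count", {
  path <- tempfile(fileext = ".obo")
  write_obo(fig2_doc, path)
  script <- paste0("import obonet; ",
                   "print(len(obonet.read_obo(", deparse(path),
                   ").nodes))")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(as.integer(out[length(out)]), length(fig2_doc$terms))
})
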