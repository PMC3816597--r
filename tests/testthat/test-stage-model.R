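test_that("the full NF chain builds a series of 66 ordered stages", {
  g <- build_graph(nf_stage_chain(66))
  s <- build_stage_series(g)
  expect_length(s$ids, 66L)
  expect_equal(stage_index(s, "NF stage 1"), 1L)
  expect_equal(stage_index(s, "NF stage 66"), 66L)
})

test_that("a single-stage document builds a series of length one", {
  g <- build_graph(nf_stage_chain(1))
  s <- build_stage_series(g)
  expect_length(s$ids, 1L)
  expect_equal(s$names, "NF stage 1")
})

test_that("the series is invariant under stanza order", {
  doc <- nf_stage_chain(20)
  set.seed(4)
  shuffled <- doc
  shuffled$terms <- doc$terms[sample(length(doc$terms))]
  s1 <- build_stage_series(build_graph(doc))
  s2 <- build_stage_series(build_graph(shuffled))
  expect_identical(s1$ids, s2$ids)
  expect_identical(s1$index, s2$index)
})

test_that("branching or cyclic stage chains are rejected by name", {
  doc <- nf_stage_chain(5)
  # second stage claiming the same predecessor as stage 2 -> branch
  branch <- obo_term("XAOT:1000099", name = "rogue stage",
                     namespace = "xenopus_developmental_stage",
                     relationships = data.frame(
                       relation = "preceded_by", target = "XAOT:1000001",
                       stringsAsFactors = FALSE))
  doc$terms[[branch$id]] <- branch
  expect_error(build_stage_series(build_graph(doc)),
               "multiple successors")

  doc2 <- nf_stage_chain(3)
  doc2$terms[[1]]$relationships <- data.frame(
    relation = "preceded_by", target = "XAOT:1000003",
    stringsAsFactors = FALSE)
  expect_error(build_stage_series(build_graph(doc2)), "cyclic|linear")
})

test_that("stage comparison follows the temporal ordinal", {
  s <- fig2_series
  expect_true(stage_leq(s, "NF stage 28", "NF stage 64"))
  expect_false(stage_leq(s, "NF stage 64", "NF stage 28"))
  expect_true(stage_leq(s, "NF stage 12", "NF stage 12"))
  # exhaustive agreement with ordinal comparison on a small series
  small <- build_stage_series(build_graph(nf_stage_chain(8)))
  for (a in small$ids) for (b in small$ids)
    expect_equal(stage_leq(small, a, b),
                 small$index[[a]] <= small$index[[b]])
  expect_error(stage_leq(s, "NF stage 28", "no such stage"),
               "not in series")
})

test_that("next_stage walks the chain and stops at the sentinel", {
  s <- fig2_series
  expect_equal(next_stage(s, "NF stage 30"),
               s$ids[stage_index(s, "NF stage 31")])
  expect_true(is.na(next_stage(s, "death")))
  for (i in seq_len(length(s$ids) - 1L))
    expect_equal(stage_index(s, next_stage(s, s$ids[i])), i + 1L)
})

test_that("term existence windows resolve against the series", {
  iv <- interval_of(fig2_graph, fig2_series, "pronephric kidney")
  expect_equal(stage_index(fig2_series, iv$start), 28L)
  expect_equal(stage_index(fig2_series, iv$end), 64L)
  iv2 <- interval_of(fig2_graph, fig2_series, "mesonephric kidney")
  expect_equal(fig2_series$names[stage_index(fig2_series, iv2$end)],
               "death")

  doc <- obo_document(terms = list(
    obo_term("XAOT:0000050", name = "no stages")))
  doc$terms <- c(nf_stage_chain(3)$terms, doc$terms)
  g <- build_graph(doc)
  s <- build_stage_series(g)
  expect_error(interval_of(g, s, "XAOT:0000050"), "incomplete")

  dup <- fig2_doc
  t <- dup$terms[[fid("tail region")]]
  t$relationships <- rbind(t$relationships, data.frame(
    relation = "starts_during", target = "XAOT:1000030",
    stringsAsFactors = FALSE))
  dup$terms[[t$id]] <- t
  g2 <- build_graph(dup)
  expect_error(interval_of(g2, fig2_series, t$id), "ambiguous")
})

test_that("interval containment agrees with stage-set enumeration", {
  s <- build_stage_series(build_graph(nf_stage_chain(8)))
  ords <- seq_along(s$ids)
  for (a in ords) for (b in a:max(ords)) for (x in ords) for (y in x:max(ords)) {
    inner <- stage_interval(s$ids[a], s$ids[b])
    outer <- stage_interval(s$ids[x], s$ids[y])
    expect_equal(interval_within(inner, outer, s),
                 all(a:b %in% x:y))
    expect_equal(interval_intersects(inner, outer, s),
                 length(intersect(a:b, x:y)) > 0)
  }
})

test_that("containment is a partial order and both ends are inclusive", {
  s <- fig2_series
  iv <- function(a, b) stage_interval(s$ids[a], s$ids[b])
  expect_true(interval_within(iv(21, 30), iv(21, 30), s))  # reflexive
  expect_false(interval_within(iv(28, 64), iv(21, 30), s))
  # antisymmetry + transitivity on a sampled triple
  expect_true(interval_within(iv(25, 28), iv(22, 30), s))
  expect_true(interval_within(iv(22, 30), iv(20, 40), s))
  expect_true(interval_within(iv(25, 28), iv(20, 40), s))
})
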