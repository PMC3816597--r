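# xaotools

Tools for the *Xenopus* Anatomy Ontology (XAO) and ontologies sharing its
OBO 1.2 flat-file dialect: parsing and writing, typed graph closures,
developmental-stage interval validation, ontology-expanded queries,
stage-restricted annotation checking, and release statistics/diffing.

## The problem

The XAO describes the anatomy and embryological development of the frogs
*Xenopus laevis* and *X. tropicalis*. Anatomical entities are organized in
a single classification (`is_a`) hierarchy, connected by partonomy
(`part_of`) and developmental lineage (`develops_from`) relations, and
anchored in time: every anatomical term carries a `starts_during` and an
`ends_during` relation to a stage of the Nieuwkoop–Faber (NF) normal
table, whose 66 stages are ordered by `preceded_by` links. That timing
backbone is what makes the ontology more than a vocabulary — it lets a
database restrict which terms a curator may attach to a gene-expression
image taken at a given stage, and it imposes consistency obligations
across related terms.

This package implements that data model for curators and database
engineers, together with the consistency rules that keep it biologically
sensible:

* a child term's existence window `[start, end]` must be the same as or
  fall within its `is_a` parent's window (rule R4);
* if X `develops_from` Y, X must first appear within or immediately after
  Y's window: `index(Y.start) ≤ index(X.start) ≤ index(next(Y.end))`
  (rule R5);
* a part's window should lie within its whole's window (rule R6, reported
  as a warning by default);
* plus completeness and hygiene rules: definitions for every term (R1),
  an `is_a` parent for every non-root term (R2), exactly one
  `starts_during`/`ends_during` pair with start ≤ end (R3), a `part_of`
  and a `develops_from` on every term or one of its `is_a` ancestors
  (R7), no dangling edge targets (R8), acyclicity of the combined
  `is_a`/`part_of`/`develops_from` graph (R9), and stage references that
  resolve in the series (R10).

Query expansion mirrors the Xenbase expression search: a query for a term
retrieves data annotated to its subtypes, its parts, and optionally its
developmental derivatives or precursors, so a search for "pronephric
kidney" also finds records annotated to "pronephric duct" or
"nephrostome".

## Worked example

The packaged worked-example ontology (`figure2_fixture()`, also shipped
as `inst/extdata/figure2.obo`) encodes the canonical pronephric-kidney
assertions: 'pronephric mesenchyme' (window NF 21–30) is a type of
'mesenchyme'; 'pronephric kidney' develops from it and exists from NF
stage 28 to NF stage 64; its tubules are parts of it; the transient
'tail region' spans NF 26–66.

```r
library(xaotools)
doc <- figure2_fixture()
g <- build_graph(doc)
s <- build_stage_series(g)

validate(g, s)
#> Valid: 86 terms checked, no violations

interval_of(g, s, "pronephric kidney")
#> [XAOT:1000028, XAOT:1000064]

check_annotation(g, s, "early distal tubule", "NF stage 37/38",
                 gene = "slc12a1")$valid
#> [1] TRUE

check_annotation(g, s, "pronephric kidney", "NF stage 10")$valid
#> [1] FALSE

sort(vapply(descendants(g, "pronephric kidney", "part_of"),
            function(i) g$terms[[i]]$name, character(1)))
#> "early distal tubule"  "early proximal tubule" "late proximal tubule"
#> "nephrostome"          "pronephric duct"
```

An annotation of *slc12a1* in the 'early distal tubule' of an NF stage
37/38 embryo is accepted because the stage lies inside the tubule's
window; an annotation to 'pronephric kidney' at NF stage 10 is rejected
because the organ does not exist yet (it appears at NF 28).

The same operations are available from the shell via the installed
`exec/xaotools` script:

```sh
xaotools validate inst/extdata/figure2.obo      # exit 0, empty table
xaotools stats inst/extdata/figure2.obo
xaotools search inst/extdata/figure2.obo heart
xaotools annotations check inst/extdata/figure2.obo corpus.tsv
```

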