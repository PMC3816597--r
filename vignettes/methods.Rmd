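---
title: "Stage-consistent anatomy ontologies: model, rules and generators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-consistent anatomy ontologies: model, rules and generators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xaotools)
```

## The data model

The package works on anatomy ontologies in the OBO 1.2 flat dialect used
by the *Xenopus* Anatomy Ontology (XAO). Three layers are distinguished:

* **Document** (`obo_document`): a faithful image of the file — the
  header plus ordered `[Term]`/`[Typedef]` stanzas. Structured tags
  (`id`, `name`, `namespace`, `def`, `synonym`, `xref`, `is_a`,
  `relationship`, `is_obsolete`) become typed fields; anything else is
  retained as an opaque line. This is the unit of serialization:
  `parse_obo(write_obo(d))` reproduces `d`, and `write_obo` emits a
  canonical tag order so identical documents yield byte-identical text.
* **Graph** (`xao_graph`): non-obsolete terms indexed by id, name and
  synonym, with every asserted edge typed by one of the six relations.
  Edges whose target is not an active term are quarantined in a
  `dangling` table rather than dropped — referential breakage is a
  finding, not noise. Obsolete stanzas are remembered but excluded from
  indices and closures.
* **Stage series** (`stage_series`): the developmental stages arranged in
  one linear chain by their `preceded_by` links, giving every stage an
  ordinal. Anatomical terms then carry inclusive existence windows
  `[starts_during, ends_during]` resolved against those ordinals.

Closures (`descendants()`, `ancestors()`, `expand_term()`) use
union-reachability over the selected relation kinds: when `is_a` and
`part_of` are both selected, a partonomy hop may follow a classification
hop. No relation-composition reasoning (and no description-logic
semantics) is attempted; union-reachability matches the retrieval
behavior an expression search needs and stays simple enough to verify
against brute force.

## The stage chain and the composite stage

The stage sub-ontology is modelled as a single linear chain: oogenesis
stages, when present, precede `NF stage 1`, and a terminal sentinel such
as `death` follows `NF stage 66` simply by being linked into the chain.
Any stage term that cannot be linked is an error — a branching or broken
`preceded_by` chain names the offending stages rather than being silently
accepted. Windows are stored by stage id and compared by ordinal; both
ends are inclusive, and there are no fractional or open-ended windows,
because the ontology only ever asserts whole stages. Adult structures are
expressed by `ends_during 'death'`, which distinguishes them from
transient embryonic structures with a bounded window.

The normal table's composite entry for stages 37 and 38 needed a
decision. The packaged chain names all 66 stages `NF stage 1` …
`NF stage 66`, one ordinal each, and attaches `NF stage 37/38` to
`NF stage 37` as an EXACT synonym. The alternative — a single merged
stage term occupying one ordinal — would leave only 65 entries between
`NF stage 1` and `NF stage 66` and shift every later ordinal by one,
breaking the expectation that stage *k* sits at ordinal *k* (an
annotation at stage 66 must be the 66th checked stage). With the synonym,
annotations staged on the composite entry (a common way images are
staged) resolve without ambiguity, and the chain arithmetic stays exact.

## The rule suite

`validate()` applies ten rules; each finding is a report row, never an
exception. The timing rules are the substance:

* **R4 (is_a containment).** For every asserted `child is_a parent` where
  both windows resolve: `index(parent.start) ≤ index(child.start)` and
  `index(child.end) ≤ index(parent.end)`. A subtype cannot exist outside
  its type.
* **R5 (lineage timing).** For `X develops_from Y`:
  `index(Y.start) ≤ index(X.start) ≤ index(Y.end) + k`, with the slack
  `k = 1` by default — a structure appears within or immediately after
  its precursor's window. The slack is configurable
  (`validation_config(r5_slack = )`) because "immediately after" is a
  convention; one stage is its literal reading.
* **R6 (part_of containment).** Same formula as R4 for `part_of`.
  Timing governs partonomy validity, but since the containment formula is
  a modelling convention rather than an asserted axiom, R6 defaults to
  *warning* severity; it can be promoted to an error in the config.

Checks are skipped, not guessed, when an involved window does not resolve
(missing or duplicated stage edges, a stage outside the series): those
conditions are themselves reported by R3 and R10, and reporting them
twice through derived rules would double-count a single curation defect.

R2 and R7 exempt whitelisted root terms (default: the CARO-style upper
node `anatomical entity`), since a root has no parent by design and the
completeness obligation ("a `part_of` and a `develops_from` on the term
or an `is_a` ancestor") cannot bottom out otherwise.

Reports are deterministic — sorted by rule code, then subject — so that
two runs on the same file are byte-identical, which matters when reports
are diffed between releases in a curation workflow.

## Query expansion and annotation checking

`expand_term()` exposes four flags: subtypes (`is_a`, on by default),
parts (`part_of` mixed with `is_a`), developmental successors (transitive
traversal *against* the `develops_from` direction — all derivatives of a
tissue), and precursors (along it). Successor expansion is transitive
rather than single-hop because an expansive search for a lineage founder
(all derivatives of the neural crest, say) is the use case; single-hop
neighborhoods are instead offered in `search_terms(include_related =)`,
where flooding the result list with an entire sub-ontology would be
unhelpful. That related-match augmentation is off by default in the
library and on in the CLI `search` command, matching how a search UI
shows relational context.

`check_annotation()` deems an annotation valid when every stage it names
(a single stage or an inclusive `start..end` range) lies within the
term's window, both ends inclusive. Partial overlap is rejected: an
annotation claiming expression at stages the structure does not exist in
is a curation error even if part of the range is fine. Stage-range
*retrieval* (`retrieve_annotations`, `filter_by_stage`) instead uses
intersection semantics — a query window should find any record touching
it. Retrieval filters on the annotation's own stage; filtering terms by
their existence window is a separate operation (`filter_by_stage`).
Unresolvable corpus rows are returned in an `unresolved` attribute,
never silently dropped.

## Release statistics and diffs

`summarize_ontology()` counts asserted lines, not inferred closure edges
— multiple `is_a` parents are real assertions and must be countable above
the term count. "Anatomical entities" are the non-obsolete terms outside
the stage series; series membership is the computable criterion for the
stage/anatomy partition. Definition-source xrefs (the bracketed list on a
`def` line) are deliberately excluded from the cross-reference count,
which tallies term-level `xref` lines only; whether published xref totals
include definition sources is not stated anywhere authoritative, so the
package picks the interpretation that matches the term-level referencing
scheme and documents it here. Diffs key terms by id, relationships by
(subject, relation, object), synonyms by (term, label, scope) and xrefs
by (term, xref); `diff_releases(a, b)` and `diff_releases(b, a)` have
swapped added/removed fields by construction.

## The generators

`generate_ontology()` builds test ontologies in which every rule holds
*by construction*: windows are assigned top-down (a child's window is
sampled inside the intersection of its parents'), and partonomy/lineage
edges are only attached to timing-compatible targets. All non-`is_a`
edges point from newer to older terms, which makes the combined subgraph
acyclic without a repair pass. Two structural nodes are always present: a
root (`anatomical entity`, whitelisted) and a scaffold
(`anatomical structure`) carrying one `part_of` and one `develops_from`,
so relational completeness (R7) holds for every descendant.

The window sampler mixes three motifs seen in real anatomy ontologies:
subtypes spanning their parent's window exactly, short-lived transient
structures, and structures persisting to the end of their parent's
window, with start stages biased early (most structures arise during
embryogenesis). A quarter of terms attach directly under the scaffold,
mimicking the many top-level organ systems. This variety is not
cosmetic: it keeps temporally disjoint and non-nested window pairs
present, which both the search behavior and the violation injector rely
on.

What the generator does **not** emulate: real anatomical nomenclature,
the XAO's actual term-count distributions, its oogenesis pre-chain, or
fragmented stage sub-series. Generated ids use a reserved `XAOT:` prefix
so fixtures can never collide with real `XAO:` identifiers. Passing
tests on generated ontologies therefore demonstrate the algebraic
correctness of the rules and closures, not their calibration against any
particular real release — the packaged worked-example ontology and the
(optional, not redistributed) pinned release checks cover that side.

`inject_violations()` applies targeted seeded mutations, one per
requested violation, and guarantees the validator's findings equal its
ledger exactly. Each mutation is chosen to trip only its own rule:
removing a definition (R1); orphaning a leaf that carries its own
`part_of`/`develops_from` (R2, so R7 stays satisfied); deleting or
retargeting one stage edge of a term (R3, R10 — harmless elsewhere
because checks involving an unresolvable window are skipped); widening a
leaf's window past exactly one parent bound (R4); adding a
timing-incompatible `develops_from` or `part_of` edge between terms with
no connecting path (R5, R6); adding a dangling edge (R8); and adding a
reverse `is_a` edge between a parent/child pair with identical windows,
which creates a two-node cycle that cannot trip the containment rule
(R9). Where no suitable pair exists, the injector first *forges* one by
retiming a leaf that nothing references — a mutation that is itself
violation-free because the new window stays inside the leaf's parents.
Mutated terms are excluded from later mutation sites within one call, so
injected violations cannot interact.

`generate_corpus()` samples expression annotations with a validity
ledger: valid rows draw a stage uniformly from the annotated term's own
window, invalid rows draw from its complement.

## Numerical and degenerate-input choices

* Ordinals are 1-based integers; all window comparisons are integer
  comparisons, so there are no tolerance questions anywhere in the rule
  suite.
* Ties in search ranking break alphabetically by term name, then id, to
  keep output stable across runs and platforms.
* A single-stage document yields a series of length 1; an empty document
  summarizes to zeros; an empty relation set in a closure returns the
  empty set (or the start term with `include_self`).
* All generators run under a caller-isolated RNG (`set.seed` on a saved
  and restored stream), so identical parameters and seed reproduce
  documents byte-for-byte without disturbing the session RNG.

## Problem sizes in the shipped tests

The property suite exercises 100 generated ontologies of 50 anatomical
terms over a 66-stage chain for validator exactness, 100 smaller DAGs
(12 terms, 15 stages) for closure/expansion oracles and round-trips, and
exhaustive interval enumeration on a 6-stage series. These sizes give
every rule and fallback path multiple firings per run while keeping the
whole suite comfortably inside a few minutes on one CPU; they are scale
models of the real ontology (which is ~25× larger), not simulations
of it.

## Known limitations

* OWL/RDF serializations, obographs JSON and remote release fetching are
  out of scope; only the flat OBO 1.2 subset is read and written.
* No cross-ontology reasoning: UBERON/CARO/CL references are carried and
  counted as opaque identifiers, and definition consistency with other
  ontologies is an editorial matter the validator cannot decide.
* The stage model insists on one linear chain. A release whose stage
  terms form several disconnected sub-series (e.g. an unlinked oogenesis
  segment) fails series construction by design; linking them is a
  curation act the package will not invent.
* Relation semantics are structural: the validator checks the asserted
  graph, and cannot tell a biologically wrong assertion from a right one
  when both are timing-consistent.
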