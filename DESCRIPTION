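Package: xaotools
Title: Parse, Validate and Query the Xenopus Anatomy Ontology
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the Xenopus Anatomy Ontology (XAO) and
    ontologies of the same OBO 1.2 flat-file dialect. Reads and writes OBO
    term stanzas losslessly enough to round-trip, builds a typed multigraph
    over the six XAO relation kinds (is_a, part_of, develops_from,
    starts_during, ends_during, preceded_by), models the Nieuwkoop-Faber
    developmental stage series as an ordered chain with per-term existence
    intervals, checks the ontology-building consistency rules that govern
    developmental timing across related terms, expands anatomy queries over
    the classification, partonomy and lineage relations the way the Xenbase
    expression search does, checks stage-restricted expression annotations,
    and produces release content summaries and inter-release diffs.
    Deterministic fixture generators build rule-conformant test ontologies,
    seeded violation injection, and annotation corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
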