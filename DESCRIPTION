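Package: ccoem
Title: Compact Coevolutionary Matching of Biomedical Ontologies
Version: 0.1.0
Authors@R:
    person("ccoem", "developers", email = "ccoem@example.org", role = c("aut", "cre"))
Description: Aligns two biomedical ontologies by combining profile-based
    concept similarity (padded character n-grams plus a pluggable synonym
    dictionary, with a delta-gated asymmetric combination rule) with a
    compact coevolutionary search.  Three probability-vector subswarms
    maximise MatchRatio, MatchCoverage and MatchFmeasure respectively and
    exchange elites each generation so that the precision and recall
    surrogates improve jointly.  Includes readers and writers for OWL
    (RDF/XML and a Turtle subset) and OAEI-style alignment files, the rough
    and reference-based alignment metrics, and a synthetic fixture
    generator producing ontology pairs with known ground-truth alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
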