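Package: triplink
Title: Joint Entity and Relation Extraction with a Single-Module Global Pointer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Joint extraction of (subject, relation, object) triples from
    character-level sentences using a single-module global-pointer tagging
    scheme: all entity-boundary and relation information for a sentence is
    stored in one L x K x L integer tensor whose cells mark head-to-head,
    tail-to-tail and head-to-tail links between token positions.  Provides
    the tag codec (encoding gold triples, decoding predicted tensors,
    including the special handling of single-character entities), a pair
    scoring head over a pluggable sentence encoder, training with Adam and
    per-cell cross-entropy, strict-match evaluation with overlap-pattern and
    per-relation breakdowns, a synthetic corpus generator covering nested
    entities and overlapping-triple patterns, and readers/writers for
    CMeIE-style JSON-lines corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
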