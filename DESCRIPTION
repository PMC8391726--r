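Package: narrastyle
Title: Stylometric and Emotion-Lexicon Analysis of Short Japanese Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing writing style and lexicon-weighted emotion
    profiles of short Japanese narratives between psychological-distress groups.
    Implements sentence-preserving truncation of free-text responses to a fixed
    character budget, stylometric measures (script-type ratios, lexical
    diversity and composition, word abstraction, sentence and dependency-chunk
    statistics), a seven-category weighted emotion profile from a JIWC-style
    lexicon, Kessler K-10 distress scoring with cutoff-based grouping, and
    Welch or pooled two-sample comparison tables, together with a seeded
    generator of annotated synthetic corpora for offline testing and
    calibration of the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
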