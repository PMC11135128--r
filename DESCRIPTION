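Package: svacoder
Title: Rule-Based Coding of Smart Voice Assistant Interaction Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Codes time-stamped smart voice assistant (SVA) interaction logs
    from older adults into twelve daily-routine categories using a modified
    rule-based natural language processing pipeline: chronological
    normalization and weekly segmentation of per-participant logs, keyword
    lexicon matching, temporal episode segmentation that merges repeated and
    continuation commands into single coded interactions, weekly
    category-by-week crosstabulation with XML export, inter-coder reliability
    (percent agreement, Cohen's kappa, discrepancy triage),
    principal-components factor analysis with varimax rotation and Kaiser
    retention for comparing coding methods, and a seeded synthetic log
    generator with ground-truth episodes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
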