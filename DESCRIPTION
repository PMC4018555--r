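Package: esnlang
Title: Echo State Network Models of Grammatical Construction Comprehension and Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Leaky echo state networks that learn grammatical constructions as
    mappings between sentence surface forms and predicate-argument meanings.
    A comprehension model maps sentences to thematic-role assignments over
    their content words (the action-performing task), and a production model
    maps coded meanings plus a canonical/non-canonical flag back to sentences
    (the scene-description task). Includes corpus readers/writers for
    sentence-meaning pairs, closed-class lexicon extraction by exclusion, a
    seeded generator of synthetic command and scene-description corpora, and
    the learnability and leave-one-out generalization evaluation protocols
    with multi-instance aggregation and per-category breakdowns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
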