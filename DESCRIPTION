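Package: readsim
Title: Simulation of Eye-Movement Control in Reading with Graded
    Predictive Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An interactive-activation model of word recognition and
    eye-movement control in continuous text reading.  Words are coded as
    sets of open bigrams; letter input is modulated by eccentricity,
    crowding and attention; lexical competitors inhibit each other in
    proportion to their orthographic overlap; and contextual predictions
    (from cloze norms or language-model next-token distributions)
    pre-activate candidate words at parafoveal positions in a graded,
    parallel and dynamic fashion.  The package simulates fixation
    sequences over passages, aggregates them into standard word-level
    eye-movement measures (skipping, first fixation duration, gaze
    duration, total reading time, regression), and scores model fit
    against human word-level data with standardized root-mean-square
    error.  A synthetic-data module generates passages, frequency
    lexica, cloze-like and language-model-like predictability tables and
    pseudo-human measures, so the entire pipeline can be exercised and
    tested without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
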