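Package: onsetfuse
Title: Spoken Word Recognition with Fused Top-Down and Bottom-Up Syllabic
    Onset Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical probabilistic decoder of spoken words (phones,
    syllables, words) over a small toy lexicon, in which syllabic parsing is
    driven by a temporal-control module that fuses bottom-up onset detection
    from the acoustic loudness envelope with top-down lexical prediction of
    syllabic onset times. Includes a synthetic stimulus generator (formant
    tracks in Bark space and parametric loudness profiles with noisy-event
    and hypo-articulation degradations), gated leaky evidence accumulators,
    AND/OR/bottom-up-only fusion variants of the onset decision, and a
    simulation campaign runner with event-detection F-score and word
    recognition probability measures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
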