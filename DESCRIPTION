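Package: alliancelang
Title: Language Markers of Therapeutic Alliance from Dyadic Session Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking dyadic language features extracted
    from two-speaker psychotherapy-style session transcripts (dictionary-based
    first-person pronoun and non-fluency frequencies, part-of-speech bigram
    transition probabilities, pronoun-anchored word bigrams) and trust-game
    repayment behavior to therapeutic-alliance ratings. Includes transcript
    parsing and cleaning, a pluggable part-of-speech tagger with a built-in
    rule tagger, a 10-round trust-game simulator with a k-nearest-neighbour
    investor policy, mass-univariate F-regression with Benjamini-Hochberg
    false-discovery-rate control, paired and rank-based role comparisons,
    partial and dependent-correlation (Steiger's Z) tests, quasi-Bayesian
    causal mediation, and a synthetic-cohort generator with planted effects
    so that every pipeline stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
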