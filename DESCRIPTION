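Package: numlearn
Title: Error-Driven Discrimination Learning of Number Words
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates how children learn the meanings of small number words
    through error-driven (Rescorla-Wagner) discrimination learning. Provides
    the learning engine with trajectory recording, a generator of synthetic
    number-learning events with nested numerosity cues and competing
    color/shape/size cues under Feature-to-Label (postnominal) and
    Label-to-Feature (prenominal) temporal arrangements, corpus-frequency
    training schedules built from spoken number-word frequencies in English
    and Spanish, read-outs of the learned state (label activations,
    discrimination scores, three-alternative forced choice), and drivers for
    simulations of sequencing effects, emergent subitization limits, and
    facilitation of untrained numbers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
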