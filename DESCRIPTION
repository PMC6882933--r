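Package: hbci
Title: Hybrid EEG/EOG Brain-Computer Interface Decoding and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested software stack for a hybrid brain-computer interface
    that steers an assistive wheelchair by motor imagery and selects GUI
    buttons by flash-synchronized eye blinks. Implements common spatial
    pattern (CSP) feature extraction with support vector machine decoding,
    idle-referenced dual-threshold steering, multi-threshold EOG blink and
    eyebrow-raise detection with flash-timing attribution, the
    preselect-verify-command selection state machine, a kinematic simulator
    of the wheelchair and robotic-arm plant, synthetic EEG/EOG generators
    with controlled event-related desynchronization, and binomial
    session-significance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
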