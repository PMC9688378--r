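Package: betatrack
Title: Synthetic Bimanual Tracking and Movement-Related Beta Desynchronization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a bimanual tracking task (dial-rotation traces, tracking-error
    scoring) and epoched multi-channel EEG with controlled beta-band power structure,
    then analyses it with complex Morlet time-frequency decomposition, dB baseline
    normalization, grand-average significance-mask extraction of movement-related
    beta desynchronization (MRBD), and a mixed-effects statistics layer (family
    selection by AIC, backward stepwise reduction, FDR-corrected pairwise contrasts,
    Spearman associations). Every stage is deterministic per seed so that injected
    effects can be recovered end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    car,
    emmeans,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
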