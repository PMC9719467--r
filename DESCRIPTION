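Package: rswaScoreR
Title: Automated SINBAR-Rule Scoring of REM Sleep Without Atonia from
    Polysomnographic Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies REM sleep without atonia (RSWA) from
    multi-channel surface EMG in overnight polysomnography. Reads EDF
    recordings together with plain-text hypnograms and arousal,
    respiratory, and snore event lists, estimates per-REM-period EMG
    baseline amplitudes from rolling-window root-mean-square minima, and
    applies the SINBAR visual scoring rules (2x-baseline activity bouts at
    15 ms resolution, 0.25 s interruption rule, tonic 30-s epochs, phasic
    and "any" 3-s mini-epochs) to produce per-channel and combined-channel
    RSWA indices, event timestamp tables, and bout statistics. Includes a
    deterministic synthetic polysomnography generator with ground-truth
    annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal
Suggests: testthat (>= 3.0.0), optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'baseline.R'
    'detection.R'
    'edf.R'
    'fixtures.R'
    'io-text.R'
    'outputs.R'
    'params.R'
    'preprocess.R'
    'rswaScoreR-package.R'
    'runconfig.R'
    'scoring.R'
    'segmentation.R'
    'summary.R'
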