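Package: rbeats
Title: Activity Inference from Artifact Handling via Roaming Beats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers human activities from the way physical artifacts are
    handled on a designated base location. Heterogeneous sensor streams
    (RFID tag gain/loss events, accelerometer magnitudes, per-frame
    template-correlation scores) are discretized into binary presence
    signals, state changes are extracted as time-stamped roaming beats,
    and a criteria-driven tracker engine infers simple, interleaved and
    concurrent activities from per-artifact beat counts, duration windows
    and a post-last-beat quantum wait. Includes a frequency-domain
    composite correlation filter for recognizing artifacts in grayscale
    frames, a ground-truthed scenario simulator with configurable dropout,
    spurious-event and jitter noise, an effectiveness evaluator, and an
    append-only context log answering identity, location, time and
    activity queries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
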