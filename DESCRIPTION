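Package: gaitscape
Title: Limit-Cycle Gaits and Once-Per-Step Control of a Powered Simplest Walker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the powered "simplest walker" bipedal model (point-mass
    hip, massless legs, push-off impulse and two-phase hip springs), finds
    periodic limit-cycle gaits over the full step-length by step-frequency
    gait space by warm-start continuation, linearizes the step-to-step return
    map by finite differences, analyzes open-loop stability and
    controllability, synthesizes once-per-step deadbeat feedback controllers,
    and generalizes them into a gain-interpolated feedback policy that tracks
    time-varying target gaits.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
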