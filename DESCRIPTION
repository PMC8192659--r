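Package: irtrack
Title: Infrared Touch-Frame Tracking and Closed-Loop Behavioral Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free toolkit for infrared touch-frame animal tracking
    and closed-loop behavioral experiment control. Models beam-break position
    detection (occlusion simulation and center-of-enclosing-rectangle
    decoding), arena layouts for looming, foot-shock, optogenetic, elevated
    plus maze and two-chamber paradigms, the closed-loop trigger state
    machines for those paradigms, escape/flight behavioral statistics
    (latency, hiding time, distance ratio, speed curves), a fiber-photometry
    delta-F/F processing chain with dark-background subtraction and
    exponential bleaching correction, piecewise inverse-bilinear grid
    calibration, and a stochastic mouse agent for end-to-end synthetic
    sessions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
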