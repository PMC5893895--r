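Package: recurtone
Title: Recurrence Quantification Analysis of Tonal Consonance
Version: 0.1.0
Authors@R: person("Recurtone", "Maintainers", email = "maintainer@example.com",
    role = c("aut", "cre"))
Description: Synthesis and nonlinear analysis of two-tone acoustic stimuli.
    Generates pure tones, mistuned just-intonation intervals and a
    glissando-against-fixed-tone sweep of the octave; quantifies their
    recurrence structure with a from-scratch recurrence quantification
    analysis (RQA) engine (time-delay embedding, Euclidean distance matrix,
    radius thresholding, percent recurrence, mutual-information lag
    selection) and a sliding-window scan (RQE) that maps percent recurrence
    onto the interval-ratio axis. Detected recurrence peaks are matched to
    small-integer frequency ratios, ranked against the classical consonance
    order, correlated with Frova's simplicity index (m+n)/(m*n), and the
    cumulative recurrence profile is compared with the Devil's staircase of
    the sine circle map at critical coupling. First- and second-order beat
    rates of mistuned intervals are measured from the amplitude envelope and
    from waveform self-similarity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
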