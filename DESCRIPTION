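Package: etspan
Title: Eye-Time Span Measurement for Metronome-Synchronized Music Reading
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Eye-Time Span (ETS), a backward-projective measure of
    how far ahead of the musical beat a reader's eyes are during temporally
    controlled music sight reading. Maps eye-tracking fixations onto a score
    treated as a metrical time scale (pixel-to-beat interpolation, area-of-
    interest assignment), anchors metrical time to the recording clock from
    metronome-aligned timestamps (circular-median click-phase estimation),
    extracts first fixations per note with the standard exclusion filters,
    converts incoming saccades to beat units, and provides the two baseline
    eye-hand span measures. Includes a stimulus and scanpath simulator with
    controllable early/distant-attraction effects for end-to-end validation,
    and a generalized estimating equations (GEE) analysis with gamma variance,
    inverse link, exchangeable working correlation, robust Wald tests and
    multiplicity-adjusted post hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    mvtnorm
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
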