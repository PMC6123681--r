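Package: onoffmotion
Title: ON/OFF Pathway Latency Asymmetries for Moving Light and Dark Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying why responses to moving light bars can lead
    responses to moving dark bars at low speeds even though dark responses are
    stronger. Implements a forward latency model in which a Gaussian stimulus
    time course is passed through ON and OFF Naka-Rushton luminance-response
    functions with a power-function spike threshold; an electrophysiology
    pipeline that bins spike trains into peristimulus time histograms, filters
    recording sites by direction selectivity, aligns time courses with a
    Gaussian-plus-line fit, and estimates dark-minus-light half-amplitude
    latency differences with bootstrap confidence intervals; a psychophysics
    pipeline that builds accuracy and reaction-time psychometric functions from
    two-alternative forced-choice motion trials, extracts contrast sensitivity,
    and runs the associated polarity comparisons; and seeded synthetic-data
    generators for both recording and trial tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
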