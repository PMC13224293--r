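Package: irmixid
Title: Identification of Mixture Components from Infrared Spectra by
    Linear Spectral Unmixing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying the molecular components of liquid- and
    gas-phase mixtures from their infrared (IR) spectra by linear
    deconvolution against a library of pure-component spectra. Implements
    least-squares and non-negative least-squares (NNLS) unmixing with
    optional ridge regularization, a brute-force pairwise convex
    interpolation baseline, top-k identification benchmarking with
    distractor and nested-basis protocols, an atom-composition candidate
    filter, cumulative explained-variance reconstruction traces for
    inferring the number of components, peak-shift robustness studies,
    misidentification profiling by molecular formula and spectral
    proximity, and computation of IR spectra from molecular-dipole time
    series via the Fourier transform of the dipole autocorrelation
    function. A seeded synthetic-spectrum generator provides gas-like
    (sharp-peak) and liquid-like (broadened, shifted) fixtures so the full
    benchmark machinery runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
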