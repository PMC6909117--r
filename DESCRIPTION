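Package: copperhvl
Title: Half-Value Layer Evaluation for CT with Copper-Pipe Absorbers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for evaluating the half-value layer (HVL) of computed
    tomography X-ray beams with the rotating-tube copper-pipe technique.
    Fits quadratic log-attenuation curves to replicate exposure series,
    extrapolates the scatter-corrected unattenuated exposure, solves for the
    HVL in mm of copper and converts it to effective energy via bundled
    NIST photon cross-section tables. Includes a semi-empirical tungsten-anode
    spectrum model with Beer-Lambert filtration and air-kerma integration, a
    desk-scale analog Monte Carlo photon transport simulator of the
    pipe-and-chamber geometry (Klein-Nishina Compton sampling), inherent
    aluminum-filtration estimation by attenuation-curve matching, paired TOST
    equivalence testing for method comparison, and a synthetic measurement
    generator for testing without instruments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
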