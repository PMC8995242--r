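Package: blochsort
Title: Bloch-Sorted Golden-Angle Radial T1rho and T1rho-Dispersion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for fast spin-lock (T1rho) relaxometry with a
    golden-angle radial gradient-echo readout. Implements
    Bloch-simulation-optimized spoke ordering ("Bloch sorting") for
    magnetization-prepared radial acquisitions, KWIC (k-space weighted
    image contrast) view-sharing reconstruction via a Kaiser-Bessel
    gridding NUFFT, readout flip-angle optimization, pixel-wise
    mono-exponential T1rho fitting and linear T1rho-dispersion fitting,
    plus digital phantoms and a forward k-space simulator so the whole
    pipeline can be exercised and validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
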