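Package: memprobe
Title: Quantitative Analysis of Environment-Sensitive Membrane Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative workflows used with solvatochromic
    membrane probes (Pro12A, NR12S, NR12A and relatives): generalized
    polarization (GP) mapping of hyperspectral vesicle images with automatic
    vesicle detection (Otsu thresholding, density-based clustering,
    eccentricity filtering) and per-vesicle GP statistics; time-dependent
    fluorescence shift (TDFS) analysis of wavelength-resolved TCSPC decays
    (multi-exponential reconvolution fitting, time-resolved emission
    spectrum reconstruction, dynamic Stokes shift and integrated relaxation
    time); bilayer-trajectory observables (probe tilt-angle distributions
    and partial density profiles); and seeded synthetic-data generators
    that emulate the microscope, TCSPC and trajectory data with ground
    truth attached.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
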