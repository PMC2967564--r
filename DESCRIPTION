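Package: isopick
Title: Model-Based Peak List Extraction from Proteomic Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Extracts peak lists (monoisotopic mass, charge and intensity of
    every detected biomolecule) from profile-mode proteomic mass spectra.
    Theoretical isotopic distributions are computed by iterative convolution
    of elemental isotope abundances for artificial sequences of a reference
    residue (Senko Averagine, leucine, or an updated Averagine), stored, and
    interpolated at any mass. A double reference model (monoisotopic peak
    when isotopes are resolved, most-likely peak plus an inverse regression
    otherwise) makes the procedure applicable from low-resolution
    SELDI/MALDI-TOF to high-resolution FTICR spectra. Includes baseline
    correction, resolution-power estimation, maximal-curve peak detection,
    a signal-dependent noise threshold, iterative subtractive fitting of
    isotopic envelopes, replicate handling with correlation-based overlap
    weighting and misalignment correction, and a synthetic-spectrum
    generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, signal
Suggests: testthat (>= 3.0.0), mzR, jsonlite, optparse, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
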