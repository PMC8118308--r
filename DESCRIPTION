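Package: crystalscope
Title: Label-Free Cholesterol Crystal Morphometry and Hyperspectral
    Composition Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cholesterol crystals in label-free
    nonlinear optical microscopy of atherosclerotic plaque. Segments
    needle-shaped crystals in second-harmonic-generation (SHG) images by
    Otsu thresholding and marker-controlled watershed, rejects overlapping
    objects, and reports crystal counts, densities and maximum-Feret
    lengths; decomposes region-of-interest spectra from hyperspectral
    stimulated-Raman-scattering (SRS) cubes against cholesterol,
    cholesteryl-ester and protein reference spectra by non-negative least
    squares, with diagnostic band detection at 3010 and 1740 cm-1;
    quantifies reflectance crystal burden as a percent of plaque area; and
    compares groups with Mann-Whitney U and t tests. Includes synthetic
    data generators with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    pracma,
    signal,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
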