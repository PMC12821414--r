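Package: pelletspec
Title: Raman Spectroscopy Quality Control of Wood Pellets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the lignin-to-cellulose (Li/Ce) ratio of wood
    pellets from spot Raman spectra and discriminates pellet producers by
    chemometrics. Implements the full analysis chain: Savitzky-Golay
    smoothing, rolling-circle (morphological opening) baseline removal,
    band-area and peak-height Li/Ce estimators over the lignin
    (1250-1700 cm-1) and cellulose (980-1150 cm-1) bands, uncentered
    principal component analysis with Mahalanobis-distance-1 group
    ellipses, and Fisher linear discriminant analysis on the leading
    component scores. A hierarchical synthetic-spectrum generator emulates
    multi-producer pellet ensembles (component peaks, fluorescence
    background, instrument profiles) so the pipeline is fully testable
    without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    signal,
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
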