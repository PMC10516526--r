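Package: semrestore
Title: Restoration of FIB-SEM Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and restoration of focused ion beam scanning
    electron microscopy (FIB-SEM) volumes. Provides per-slice sharpness
    scoring with a Laplacian-of-Gaussian focus metric, Fourier ring
    correlation (FRC) as a restoration-acceptance criterion, corrections for
    charge gradients (rolling-ball background), milling stripes (Fourier
    wedge suppression refined by compressed sensing with total-variation
    minimisation), defocus (spectral PSF estimation and Richardson-Lucy
    deconvolution), and stage drift (multi-scale cross-correlation
    registration), plus four structural inpainting algorithms (multiscale,
    DCT penalised least squares, harmonic, total variation) to rebuild
    slices too degraded to correct. A synthetic phantom generator and an
    end-to-end restoration pipeline with FRC validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    parallel,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
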