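Package: cartrelax
Title: Low-Field and Variable-Field NMR Relaxometry of Articular Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing proton and deuteron relaxation in hydrated
    biological tissue, with articular cartilage as the model system. The
    package simulates FID-CPMG inversion-recovery experiments and fast
    field-cycling T1 dispersion profiles from known relaxation-component
    distributions, inverts recovery-by-decay signal matrices into T1-T2
    correlation maps by a Tikhonov-regularized non-negative inverse Laplace
    transform with a mixed Gaussian/exponential transverse kernel, quantifies
    the resulting peaks, fits power-law dispersions and quadrupolar-dip areas,
    and models hydration dependence through fast-exchange surface relaxation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
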