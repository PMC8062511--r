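Package: stentmech
Title: Reduced-Order Mechanics of Coronary Stent Deployment and Design Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parametric generation of ring-and-link coronary stent lattices,
    hyperelastic and elastoplastic constitutive models for arterial wall,
    atherosclerotic plaque, platinum-chromium stent alloy and semi-compliant
    balloons, a seeded generator of left-main-like bifurcation vessel
    geometries with homogeneous or heterogeneous plaque stiffness zones, a
    reduced-order quasi-static solver for balloon-driven stent expansion,
    recoil and radial crimping, and the morphometric and biomechanical
    performance metrics used to compare stent designs (mean stent diameter,
    circular cell diameter, vessel prolapse, stent-to-artery ratio,
    normalized hoop force and radial strength), together with a factorial
    experiment runner and the associated statistical comparisons.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    tibble,
    dplyr,
    readr,
    tidyr,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
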