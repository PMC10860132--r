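Package: sabrekin
Title: Spin-Order Transfer Simulation and J-Coupling Kinetics for SABRE
    Iridium-Hydride Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density-matrix simulation of parahydrogen-derived spin-order
    transfer (PASADENA read-out, SEPP and SEPP-SPINEPT selective INEPT
    sequences) in small spin-1/2 systems, together with the estimation
    machinery needed to extract sub-Hz proton-carbon J couplings and complex
    lifetimes from spin-order-transfer kinetics: a seeded synthetic-kinetics
    generator built on the damped-sinusoid signal model
    A*sin(2*pi*J*tau)*exp(-2*tau*R), single-dataset and global nonlinear
    least-squares fitting with shared J and R parameters, and decomposition
    of the fitted decay rate into dissociation kinetics with Eyring
    activation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
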