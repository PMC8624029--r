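Package: vitreokin
Title: Compartmental Pharmacokinetics of Ocular Drug Delivery from a
    Sustained-Release Hydrogel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear compartmental pharmacokinetic models of vancomycin
    transport into the vitreous humor from a thermo-responsive hydrogel
    drug delivery system placed topically, subconjunctivally,
    intravitreally, or subretinally. Provides the logarithmic
    hydrogel-release input function with least-squares fitting and
    release-profile summaries (encapsulation efficiency, initial burst,
    cumulative release), route-specific compartment graphs with
    literature rate constants, stiff ODE simulation with
    threshold-crossing and peak detection in the vitreous, calibration
    of the delivery-system outflow rate against the intravitreal peak,
    and synthetic-data generators for end-to-end parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
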