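Package: lipofluct
Title: Charge-Fluctuation Model of DNA Condensation in Cationic Lipid Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical-thermodynamics model of divalent-cation
    charge-fluctuation attraction between lipid-bound DNA duplexes, with the
    supporting electrolyte electrostatics (ionic strength, Bjerrum and Debye
    lengths, ion-ion coupling parameter), frame-based trajectory-style
    observables (concentration profiles, solvation-shell charge decomposition,
    coordination and contact censuses, radial distribution functions),
    coordinate-based X-ray scattering with lamellar Bragg-peak readout, and a
    synthetic-configuration generator for membrane-DNA-MgCl2 systems so that
    every analysis is testable without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
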