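Package: camdecode
Title: Decoding Calcium Signatures Through Calmodulin-CAMTA Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action model of the cytosolic Ca2+-calmodulin-CAMTA binding
    network (19 species, 33 reactions) with thermodynamically consistent
    derivation of unmeasured rate constants from detailed balance, stiff ODE
    simulation under clamped calcium inputs, and a delayed Hill-type gene
    expression stage. Includes generators for square-wave (piecewise) and
    smooth synthetic calcium signatures, equilibrium amplification analysis,
    signature decoding into mRNA fold changes, potential-versus-actual
    expression history curves, oscillation period and duration scans, and
    calibration of the total calmodulin concentration against an expression
    anchor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
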