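Package: hepaflow
Title: Lumped-Parameter Haemodynamic Modelling of the Hepatic Arterial
    Supply for Surgical Clamp Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-specific reduced-order (zero-dimensional) modelling of
    the celiac/hepatic arterial circulation. Vessel segments carry
    Hagen-Poiseuille resistances, outlets carry two-parameter Windkessel
    boundary conditions, and steady flows are solved on the resulting
    resistance network under a fixed aortic inlet pressure. Outlet
    resistances are calibrated to intraoperative transit-time flow
    measurements, after which gastroduodenal or common hepatic artery
    clamping is simulated to predict proper hepatic artery inflow with
    probe-variability prediction intervals. Includes anatomy templates
    (Michels type I, celiac-trunk stenosis, replaced right hepatic artery),
    a seedable synthetic-patient generator, embedded clinical validation
    tables, and the accuracy statistics used to evaluate predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
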