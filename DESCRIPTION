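Package: aqdyn
Title: Lumped-Parameter Modeling of Aqueous Humor Dynamics and Intraocular
    Pressure
Version: 0.1.0
Authors@R:
    person("aqdyn", "developers", email = "aqdyn@example.org", role = c("aut", "cre"))
Description: A steady-state, zero-dimensional (electric-analog) hydraulic
    circuit model of aqueous humor secretion, circulation and drainage in
    the anterior segment of the human eye.  Intraocular pressure (IOP) is
    computed as the fixed point of a nonlinear iteration map obtained from
    Kirchhoff current balance and Ohm/Darcy constitutive laws.  Drainage is
    split between a linear conventional (trabecular) route and an
    unconventional (uveoscleral) route whose hydraulic conductance and
    drug-driven flow source follow Hill-type saturation laws.  The package
    calibrates all conductances from baseline physiology, solves
    physiological and pathological (elevated trabecular resistance)
    scenarios, simulates a daily topical-drug regimen, and provides an
    independent bracketed root-finding oracle, a contraction diagnostic,
    a closed-form sensitivity of IOP to trabecular resistance, and a mass
    conservation audit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
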