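Package: vasoadapt
Title: Biochemomechanical Simulation of Arterial Growth and Remodeling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates flow- and pressure-induced adaptation of a
    cylindrical artery over weeks to months by coupling a two-compartment
    model of collagen turnover (mechano-regulated procollagen synthesis,
    an intermediate microfibril pool, maturation into cross-linked fibers,
    and tension-dependent removal) to a constrained-mixture membrane model
    of the wall with four collagen fiber families, passive smooth muscle,
    permanent elastin, and shear-regulated smooth muscle tone. Provides
    heredity-integral cohort bookkeeping with exponential survival
    functions, a Newton solve of circumferential equilibrium at each time
    step, scenario construction for step and ramp perturbations of
    normalized pressure and flow, an analytic ideal-adaptation (cube-root
    law) calculator, active stress-stretch diagnostics, and a command-line
    driver for parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
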