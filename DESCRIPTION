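Package: coroflow
Title: Closed-Loop Simulation of Cardiac-to-Coronary Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Beat-to-beat closed-loop simulation of the human circulation with a
    mechanistic coronary module. Ventricular mechanics follow a one-fiber
    myofiber model with three-wall (TriSeg) ventricular interaction and a
    non-linearly compliant pericardium; large systemic, pulmonary and coronary
    conduit vessels are non-linear elastic tube elements with wave impedance;
    each coronary branch (LAD, LCx, RCA) perfuses a three-layer lumped
    microcirculation whose vessels obey a collapsible-tube pressure-area law
    and volume-dependent Poiseuille resistances. Coronary perfusion is coupled
    to cardiac contraction through a transmurally varying intramyocardial
    pressure composed of cavity-induced extracellular pressure and a fiber
    stress dependent stiffness term. Includes homeostatic pressure/flow
    control, coronary autoregulation tuning to target branch flows, an aortic
    valve stenosis scenario, and waveform metrics (peak diastolic-to-systolic
    velocity ratio, diastolic velocity-time-integral fraction, transmural
    diameter changes, transvalvular gradients).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
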