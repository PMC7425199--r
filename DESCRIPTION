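Package: mamyo
Title: Mouse Atrial Myocyte Electrophysiology Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ordinary-differential-equation model of the mouse
    atrial myocyte action potential and intracellular calcium handling.
    Membrane ion channels with rich gating kinetics (L-type calcium current,
    transient-outward, ultra-rapid and rapid delayed-rectifier potassium
    currents, ryanodine receptor) are formulated as Markov chains; calcium is
    resolved in four compartments (dyadic cleft, sub-sarcolemmal shell, bulk
    cytosol, sarcoplasmic reticulum) with explicit buffering, SERCA reuptake
    under CaMKII-dependent scaling, and left/right atrial variants. Includes
    declarative protocol engines (pacing, voltage clamp, S1S2 restitution,
    caffeine dump, ion clamp, drug block), feature extraction for action
    potentials and calcium transients, and a command-line interface. The stiff
    system is integrated with deSolve using a compiled right-hand side.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
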