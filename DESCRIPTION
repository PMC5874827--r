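Package: cnspbpk
Title: Regional Brain Physiologically Based Pharmacokinetic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-body physiologically based pharmacokinetic (PBPK)
    simulation for rat and human with a five-compartment regional central
    nervous system sub-model (intracranial blood, rest-of-brain,
    hippocampus, frontal cortex and cerebrospinal fluid). Includes in
    vitro-in vivo extrapolation of hepatic and renal clearance
    (well-stirred liver, microsomal and hepatocyte scale-up, glomerular
    filtration rate correction), scaling of in vitro apparent permeability
    to blood-brain barrier permeability-surface-area products, Monte Carlo
    propagation of regional extracellular-fluid volume uncertainty,
    permeability sensitivity sweeps, and non-compartmental summaries
    (Cmax, tmax, AUC, Kp_brain, Kp_uu_brain, fold-error statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
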