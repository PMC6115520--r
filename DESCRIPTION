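Package: emuflux
Title: Steady-State 13C Metabolic Flux Analysis via Elementary Metabolite Units
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steady-state 13C-isotope tracer analysis of microbial
    central carbon metabolism. Implements GC-MS mass-isotopomer processing
    (normalization, natural-abundance correction, fractional labeling),
    forward simulation of amino-acid labeling on atom-mapped metabolic
    networks by elementary metabolite unit (EMU) decomposition with an
    exhaustive isotopomer oracle, local flux-ratio estimators at pathway
    branch points, and global flux estimation by weighted sum-of-squared
    residual minimization with profile-likelihood confidence intervals.
    Ships an atom-mapped model of the Clostridium thermocellum central
    carbon network and a synthetic tracer-experiment generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
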