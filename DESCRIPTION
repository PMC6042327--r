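Package: sgtadimer
Title: Integrative Biophysics of Open and Closed States of a Multidomain Homodimer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Coarse-grained conformer generation and forward/inverse analysis for
    the four solution techniques used to probe C-terminal closure of the SGTA
    co-chaperone homodimer: small-angle X-ray scattering (Debye forward model,
    Guinier analysis, regularized indirect transform, Porod volume, Kratky
    transform, genetic-algorithm ensemble selection), double electron-electron
    resonance (dipolar kernel simulation and non-negative Tikhonov inversion),
    NMR spin relaxation (exponential decay fits, per-domain rotational
    correlation times, heteronuclear NOE, chemical-shift perturbation and
    chemical-shift-index profiles), and native mass spectrometry (charge-state
    deconvolution, oligomer assignment, repeated-adduct ladder detection). A
    workbench orchestrates a virtual open-versus-closed experiment across all
    four techniques with fully seeded, reproducible synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    MASS,
    minpack.lm,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
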