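Package: psphot
Title: Photophysical Evaluation of Photodynamic-Therapy Photosensitizers
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-electronic-structure analysis pipeline for evaluating
    organic photosensitizers for photodynamic therapy. Starting from
    quantum-chemistry-level inputs (vertical excitation energies and
    oscillator strengths, spin-orbit couplings, excited-state decay rate
    constants, two-photon transition strengths, electron-transfer
    energetics and binding free energies) the package computes polyprotic
    acid-base speciation and molar fractions, assembles one-photon
    absorption spectra, converts two-photon transition strengths into
    cross sections with single-beam degeneracy and lineshape corrections,
    totals intersystem-crossing rates into triplet quantum yields and
    lifetimes, gates Type II singlet-oxygen feasibility on the T1-S0
    energy gap, evaluates Marcus-theory activation energies and Eyring
    rate constants for Type I/III electron-transfer reactions, builds
    full electron donor-acceptor maps, and converts intercalation free
    energies into DNA binding constants. A fully worked anthraquinone
    (aloe-emodin) dataset is bundled, together with a seeded synthetic
    dataset generator for testing every stage without any
    electronic-structure run.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
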